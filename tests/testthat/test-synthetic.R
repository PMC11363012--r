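# Population generator and measurement simulator.

test_that("presets encode the reported population structure", {
  for (p in preset_labels()) {
    cfg <- build_preset(p)
    props <- vapply(cfg$cell_types, function(ct) ct$proportion, numeric(1))
    expect_equal(sum(props), 1, tolerance = 1e-12)
    d <- do.call(rbind, lapply(cfg$cell_types, function(ct) ct$diameter_range))
    expect_true(all(d >= 16 & d <= 45))
  }
  leaf <- build_preset("leaf-SA")
  idx <- vapply(leaf$cell_types, function(ct) ct$name, character(1))
  expect_equal(leaf$cell_types[[which(idx == "idioblast")]]$proportion, 0.025)
  expect_equal(leaf$n_cells, 202L)
  expect_equal(build_preset("root-SA")$n_cells, 187L)
  expect_equal(build_preset("petal-SA")$n_cells, 232L)
  expect_error(build_preset("stem-SA"), "unknown preset")
})

test_that("the root preset carries no flavonoid or anthocyanin compounds", {
  lib <- cr_compound_library()
  flav <- lib$name[lib$class %in% c("flavonoid", "anthocyanin")]
  root <- build_preset("root-SA")
  used <- unlist(lapply(root$cell_types, function(ct) ct$profile$compound))
  expect_length(intersect(used, flav), 0)
})

test_that("in the LBE petal, secologanin presence implies flavonoid presence", {
  lib <- cr_compound_library()
  flav <- lib$name[lib$class == "flavonoid"]
  for (ct in build_preset("petal-LBE")$cell_types) {
    pr <- ct$profile
    if (any(pr$compound == "secologanin" & pr$presence > 0)) {
      expect_true(any(pr$compound %in% flav & pr$presence == 1))
    }
  }
})

test_that("generation is reproducible, respects n_cells = 0, and draws types binomially", {
  cfg <- build_preset("leaf-SA")
  p1 <- generate_population(cfg, seed = 5)
  p2 <- generate_population(cfg, seed = 5)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$truth, p2$truth)
  expect_false(identical(p1$truth, generate_population(cfg, seed = 6)$truth))

  cfg$n_cells <- 0L
  empty <- generate_population(cfg, seed = 1)
  expect_equal(nrow(empty$cells), 0)

  # binomial(10000, 0.025) oracle: 3 sigma around 250 is [203, 297]
  cfg$n_cells <- 10000L
  big <- generate_population(cfg, seed = 2)
  n_idio <- sum(big$cells$true_type == "idioblast")
  sd3 <- 3 * sqrt(10000 * 0.025 * 0.975)
  expect_gt(n_idio, 250 - sd3)
  expect_lt(n_idio, 250 + sd3)
  expect_true(all(big$truth >= 0))
  expect_true(all(big$cells$diameter >= 16 & big$cells$diameter <= 45))
})

test_that("invalid cell-type specs are rejected", {
  prof <- data.frame(compound = "x", presence = 0.5, low = 1, high = 2)
  expect_error(cell_type_spec("a", 1.2, c(16, 45), prof), "proportion")
  expect_error(cell_type_spec("a", 0.5, c(45, 16), prof), "diameter_range")
  bad <- prof; bad$low <- 3
  expect_error(cell_type_spec("a", 0.5, c(16, 45), bad), "bounds")
  half <- cell_type_spec("a", 0.5, c(16, 45), prof)
  expect_error(population_config("t", "c", list(half), 10), "sum to 1")
})

test_that("noiseless measurement is exactly response_factor times well amount", {
  inst <- noiseless_instrument(library = tiny_library())
  cfg <- population_config("leaf", "SA", n_cells = 5, cell_types = list(
    cell_type_spec("only", 1, c(20, 40), data.frame(
      compound = c("secologanin", "catharanthine"), presence = 1,
      low = c(50, 10), high = c(600, 300)))))
  pop <- generate_population(cfg, seed = 3)
  meas <- simulate_measurement(pop, inst, seed = 4)
  vol <- cell_volume_from_diameter(pop$cells$diameter)
  for (cmp in c("secologanin", "catharanthine")) {
    amount <- pop$truth[, cmp] * vol * 1e-15
    fid <- match_known_compounds(meas$table, inst$library)$feature_id[
      match_known_compounds(meas$table, inst$library)$compound == cmp]
    expect_equal(unname(meas$table$areas[fid, ]),
                 unname(inst$response_factor[[cmp]] * amount))
  }
  # internal standard present with the nominal area in every sample
  asn <- match_known_compounds(meas$table, inst$library)
  is_fid <- asn$feature_id[asn$compound == "ajmaline"]
  expect_true(all(meas$table$areas[is_fid, ] == inst$is_area))
})

test_that("a cell's areas depend only on that cell when contamination is off", {
  inst <- noiseless_instrument(library = tiny_library())
  cfg <- population_config("leaf", "SA", n_cells = 6, cell_types = list(
    cell_type_spec("only", 1, c(20, 40), data.frame(
      compound = "secologanin", presence = 0.5, low = 10, high = 100))))
  pop <- generate_population(cfg, seed = 9)
  meas <- simulate_measurement(pop, inst, seed = 10)
  # zero a different cell's truth: cell 1's areas must not change
  pop2 <- pop
  pop2$truth[2, ] <- 0
  meas2 <- simulate_measurement(pop2, inst, seed = 10)
  expect_equal(meas$table$areas[, 1], meas2$table$areas[, 1])
})

test_that("cross-contamination adds a small carry-over from another cell", {
  inst <- noiseless_instrument(library = tiny_library())
  types <- list(
    cell_type_spec("hot", 0.5, c(30, 30), data.frame(
      compound = "catharanthine", presence = 1, low = 100, high = 100)),
    cell_type_spec("cold", 0.5, c(30, 30), data.frame(
      compound = "secologanin", presence = 1, low = 50, high = 50)))
  cfg <- population_config("leaf", "SA", types, n_cells = 40,
                           cross_contamination_rate = 1)
  pop <- generate_population(cfg, seed = 12)
  meas <- simulate_measurement(pop, inst, seed = 13)
  asn <- match_known_compounds(meas$table, inst$library)
  cat_fid <- asn$feature_id[asn$compound == "catharanthine"]
  cold <- pop$cells$true_type == "cold"
  # some cold cells picked up catharanthine from a hot donor
  expect_gt(sum(meas$table$areas[cat_fid, cold] > 0), 0)
})

test_that("calibration series are monotone when noiseless and reproducible when noisy", {
  inst0 <- noiseless_instrument(library = tiny_library())
  s0 <- simulate_calibration_series(inst0, levels = 10^seq(-3, 1), seed = 1)
  for (d in split(s0, s0$compound)) {
    expect_true(all(diff(d$area[order(d$level)]) >= 0))
  }
  inst <- instrument_config(library = tiny_library())
  s1 <- simulate_calibration_series(inst, seed = 7)
  s2 <- simulate_calibration_series(inst, seed = 7)
  expect_identical(s1$area, s2$area)
  expect_false(identical(s1$area,
                         simulate_calibration_series(inst, seed = 8)$area))
  expect_error(simulate_calibration_series(inst, levels = numeric(0)),
               "nonempty")
  expect_error(simulate_calibration_series(inst, levels = c(1, 0.1)),
               "sorted")
})
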