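# Calibration, internal-standard normalization, geometry, and the
# area -> amount -> in-cell concentration chain.

test_that("noiseless calibration recovers the line exactly", {
  levels <- rep(c(0.1, 0.5, 1, 5, 10), each = 2)
  curve <- fit_calibration(levels, 2 * levels)
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 0, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$linear_range, c(0.1, 10))
  expect_equal(curve$loq, 0.1 * 12 * 1e-12)
})

test_that("a saturated top level is excluded by the back-calculation filter", {
  levels <- c(0.1, 0.5, 1, 5, 10, 50)
  areas <- 2 * levels
  areas[6] <- areas[5] * 1.1   # detector saturation: top level flattens
  curve <- fit_calibration(levels, areas)
  expect_equal(curve$linear_range[2], 10)
  expect_equal(curve$loq_level, 0.1)
})

test_that("degenerate calibrations fail loudly", {
  expect_error(fit_calibration(c(1, 2, 3), c(5, 5, 5)), "calibration failed")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(fit_calibration(c(0, 1, 2), c(0, 1, 2)), "must be > 0")
})

test_that("internal-standard normalization rescales per sample", {
  areas <- matrix(c(100, 200, 300,
                    10, 10, 10), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("c1", "c2", "c3")))
  ft <- feature_table(data.frame(feature_id = c("F1", "IS"),
                                 mz = c(100, 327.2), rt = c(50, 165)), areas)
  # all IS areas equal -> unchanged
  expect_equal(normalize_internal_standard(ft, "IS")$areas, ft$areas)

  areas2 <- areas; areas2[2, 2] <- 20   # doubled IS -> halved areas
  ft2 <- feature_table(ft$features, areas2)
  norm <- normalize_internal_standard(ft2, "IS")
  expect_equal(unname(norm$areas["F1", "c2"]), 100)
  expect_equal(unname(norm$areas["F1", c("c1", "c3")]), c(100, 300))

  areas3 <- areas; areas3[2, 3] <- 0    # zero IS -> sample excluded
  ft3 <- feature_table(ft$features, areas3)
  expect_warning(norm3 <- normalize_internal_standard(ft3, "IS"), "c3")
  expect_identical(norm3$samples, c("c1", "c2"))
  expect_equal(norm3$areas["F1", ], ft$areas["F1", c("c1", "c2")])
})

test_that("sphere volumes from diameters are correct and scale cubically", {
  expect_equal(cell_volume_from_diameter(20), 4.18879, tolerance = 1e-6)
  expect_equal(cell_volume_from_diameter(30), 14.13717, tolerance = 1e-6)
  d <- runif(20, 16, 45)
  expect_equal(cell_volume_from_diameter(2 * d),
               8 * cell_volume_from_diameter(d))
  expect_error(cell_volume_from_diameter(0), "diameter")
})

test_that("area to amount inverts the calibration line with unit tracking", {
  # response 1e15 area/mol in a 12 uL extract -> slope 12000 area per uM
  curve <- fit_calibration(c(1e-3, 1e-2, 0.1, 1, 10),
                           12000 * c(1e-3, 1e-2, 0.1, 1, 10))
  res <- area_to_cell_amount(1000, curve, extract_volume = 12)
  expect_equal(res$amount, 1e-12, tolerance = 1e-9)  # 1.0 pmol
  expect_equal(res$flag, "quantified")

  # area exactly at the LOQ level's fitted area -> amount = loq, quantified
  at_loq <- area_to_cell_amount(12000 * 1e-3, curve)
  expect_equal(at_loq$amount, curve$loq)
  expect_equal(at_loq$flag, "quantified")

  expect_equal(area_to_cell_amount(0, curve)$flag, "below_loq")
  expect_true(is.na(area_to_cell_amount(0, curve)$amount))
  expect_equal(area_to_cell_amount(12000 * 100, curve)$flag, "above_range")
})

test_that("amount over volume gives the documented concentrations", {
  expect_equal(cell_concentration(1e-12, 4.18879), 238.7, tolerance = 1e-3)
  expect_equal(cell_concentration(1e-12, 14.13717), 70.73, tolerance = 1e-3)
  expect_identical(cell_concentration(0, 5), 0)
  expect_error(cell_concentration(1e-12, 0), "volume")
})

test_that("noiseless simulate -> quantify round trip is the identity", {
  for (preset in c("leaf-SA", "root-SA", "petal-LBE")) {
    run <- quantify_preset(preset, seed = 21, instrument = noiseless_instrument())
    truth <- run$population$truth
    conc <- run$quant$concentration
    status <- run$quant$status
    common <- intersect(colnames(truth), colnames(conc))
    for (cmp in common) {
      q <- status[, cmp] == "quantified"
      expect_true(all(abs(conc[q, cmp] - truth[q, cmp]) /
                        truth[q, cmp] < 1e-9))
      # censored nonzero entries really are below the curve LOQ
      vol <- run$quant$volume
      below <- status[, cmp] == "below_loq" & truth[, cmp] > 0
      if (any(below)) {
        expect_true(all(truth[below, cmp] * vol[below] * 1e-15 <
                          run$curves[[cmp]]$loq * (1 + 1e-9)))
      }
    }
    # absent entries correspond to zero truth
    for (cmp in common) {
      expect_true(all(truth[status[, cmp] == "absent", cmp] == 0))
    }
  }
})

test_that("concentration times volume equals amount for quantified entries", {
  run <- quantify_preset("leaf-SA", seed = 31)   # default noisy instrument
  q <- run$quant
  idx <- which(q$status == "quantified", arr.ind = TRUE)
  expect_gt(nrow(idx), 50)
  lhs <- unname(q$concentration[idx] * q$volume[idx[, 1]] * 1e-15)
  expect_equal(lhs, q$amount[idx], tolerance = 1e-12)
})

test_that("per-sample response drift is undone by IS normalization", {
  # rescaling one sample's areas together with its internal standard must
  # leave that sample's quantified concentrations unchanged
  run <- quantify_preset("leaf-SA", seed = 41, n_cells = 40)
  tab <- run$table
  areas <- tab$areas
  is_fid <- run$assignments$feature_id[run$assignments$compound == "ajmaline"]
  j <- which.max(areas[is_fid, ])   # scaling the top sample keeps the median
  areas[, j] <- areas[, j] * 3
  scaled <- feature_table(tab$features, areas, seed = tab$seed)
  meta <- run$quant$metadata
  q2 <- quantify_cells(scaled, meta, run$curves, run$assignments,
                       cr_compound_library())
  q1 <- run$quant
  idx <- q1$status == "quantified" & q2$status == "quantified"
  expect_gt(sum(idx), 20)
  expect_equal(q2$concentration[idx], q1$concentration[idx],
               tolerance = 1e-9)
})

test_that("concentration increases with area at fixed diameter", {
  curve <- fit_calibration(c(0.01, 0.1, 1, 10), 12000 * c(0.01, 0.1, 1, 10))
  areas <- c(200, 500, 1000, 5000)
  amt <- area_to_cell_amount(areas, curve)$amount
  conc <- cell_concentration(amt, cell_volume_from_diameter(25))
  expect_true(all(diff(conc) > 0))
})

test_that("monoprotic-base solubility follows the closed form", {
  expect_equal(max_base_solubility(0.01, 7, 7), 0.02)
  expect_equal(max_base_solubility(0.01, 7, 5), 1.01)
  expect_identical(max_base_solubility(0, 7, 5), 0)
  # catharanthine-like bound: ~20 mM at pH 5 flags the >100 mM cells
  run <- quantify_preset("leaf-SA", seed = 51,
                         instrument = noiseless_instrument())
  s0 <- 0.02 / (1 + 10^(6.95 - 5))
  flags <- flag_supersaturated(run$quant,
                               data.frame(compound = "catharanthine",
                                          s0 = s0, pka = 6.95), pH = 5)
  lim_mm <- 1e3 * max_base_solubility(s0, 6.95, 5)
  conc <- run$quant$concentration[, "catharanthine"]
  hot <- !is.na(conc) & conc > lim_mm &
    run$quant$status[, "catharanthine"] == "quantified"
  expect_equal(unname(flags[, "catharanthine"]), unname(hot))
  expect_gt(sum(flags), 0)   # some idioblasts exceed the solubility bound
})
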