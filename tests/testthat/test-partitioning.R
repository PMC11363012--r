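# Transformation, clustering, marker annotation and population summaries.

test_that("log-volume normalization behaves as documented", {
  areas <- matrix(0, 3, 2)
  vols <- c(1, 2, 4)
  expect_true(all(log_volume_normalize(areas, vols, pseudocount = 1) == 0))
  expect_true(all(log_volume_normalize(areas, vols, pseudocount = 0.1) ==
                    log10(0.1)))
  a2 <- matrix(10, 3, 2)
  t1 <- log_volume_normalize(a2, vols)
  t2 <- log_volume_normalize(a2, 2 * vols)
  expect_true(all(t2 < t1))   # larger volume -> lower normalized value
  # area == volume, pseudocount -> 0 gives log10(1) = 0
  expect_equal(log_volume_normalize(matrix(5, 1, 1), 5, pseudocount = 1e-12),
               matrix(log10(1 + 1e-12), 1, 1))
  expect_error(log_volume_normalize(a2, c(1, -1, 2)), "volumes")
})

test_that("hierarchical clustering merges identical cells first", {
  x <- rbind(c(0, 0), c(0, 0), c(10, 10))
  hc <- hierarchical_cluster(x)
  expect_equal(hc$hclust$height[1], 0)
  expect_true(tree_contains_clade(hc$hclust, c(1, 2)))
  expect_error(hierarchical_cluster(x[1, , drop = FALSE]), "at least 2")
  # deterministic leaf order on reruns
  expect_identical(hc$order, hierarchical_cluster(x)$order)
})

test_that("noiseless leaf idioblasts form a single subtree", {
  run <- quantify_preset("leaf-SA", seed = 61,
                         instrument = noiseless_instrument())
  tab <- run$table
  areas <- t(tab$areas)
  mat <- log_volume_normalize(areas, run$quant$volume)
  hc <- hierarchical_cluster(mat)
  idio <- which(run$population$cells$true_type == "idioblast")
  expect_gt(length(idio), 1)
  expect_true(tree_contains_clade(hc$hclust, idio))
})

test_that("k-means is seeded, reproducible, and exact on separated blobs", {
  set.seed(77)
  centers <- matrix(c(0, 0, 20, 0, 0, 20, 20, 20), ncol = 2, byrow = TRUE)
  truth <- rep(1:4, each = 25)
  x <- centers[truth, ] + matrix(rnorm(200, sd = 0.3), ncol = 2)
  res <- kmeans_cluster(x, k = 4, seed = 3)
  expect_true(same_partition(res$labels, truth))
  expect_identical(res$labels, kmeans_cluster(x, k = 4, seed = 3)$labels)

  one <- kmeans_cluster(x, k = 1, seed = 1, standardize = FALSE)
  expect_equal(one$tot_withinss, sum(scale(x, scale = FALSE)^2))
  expect_error(kmeans_cluster(x[1:3, ], k = 5), "exceeds")
})

test_that("marker rules annotate idioblast and IPAP cells correctly", {
  run <- quantify_preset("leaf-SA", seed = 71,
                         instrument = noiseless_instrument())
  types <- annotate_cell_types(run$quant)
  truth <- run$population$cells$true_type
  expect_true(all(types[truth == "idioblast"] == "idioblast"))
  expect_true(all(types[truth == "ipap"] == "IPAP"))
  expect_true(all(types[truth == "idioblast"] == "idioblast") &&
                sum(types == "idioblast") == sum(truth == "idioblast"))
  expect_true(all(types[!truth %in% c("idioblast", "ipap")] == "other"))

  expect_error(
    annotate_cell_types(run$quant,
                        data.frame(marker = "nonexistent", threshold = 1,
                                   label = "x")),
    "unknown marker")
  expect_error(
    annotate_cell_types(run$quant,
                        data.frame(marker = c("serpentine", "secologanin"),
                                   threshold = 1, label = c("a", "a"))),
    "unique")
})

test_that("population summaries censor below-LOQ entries and sum alkaloids", {
  run <- quantify_preset("leaf-SA", seed = 81,
                         instrument = noiseless_instrument())
  s <- population_summary(run$quant, thresholds = c(secologanin = 50))
  expect_true(all(s$compounds$frac_quantified >= 0 &
                    s$compounds$frac_quantified <= 1))
  seco <- s$compounds[s$compounds$compound == "secologanin", ]
  expect_gt(seco$frac_above_threshold, 0.25)
  expect_lt(seco$frac_above_threshold, 0.35)

  # total alkaloid per cell is at least each constituent
  lib <- cr_compound_library()
  alk <- lib$name[lib$class == "alkaloid"]
  conc <- run$quant$concentration[, alk]
  conc[run$quant$status[, alk] != "quantified" | is.na(conc)] <- 0
  expect_true(all(s$cells$total_alkaloid_mM + 1e-9 >= conc))
  expect_equal(s$cells$total_alkaloid_mM, unname(rowSums(conc)))

  # all-censored matrix: zero fractions, undefined maxima
  q0 <- run$quant
  q0$status[] <- "below_loq"
  q0$concentration[] <- NA_real_
  s0 <- population_summary(q0)
  expect_true(all(s0$compounds$frac_quantified == 0))
  expect_true(all(is.na(s0$compounds$max_mM)))

  # single cell: median equals maximum
  q1 <- run$quant
  q1$concentration <- q1$concentration[1, , drop = FALSE]
  q1$status <- q1$status[1, , drop = FALSE]
  s1 <- population_summary(q1)
  expect_equal(s1$compounds$median_mM, s1$compounds$max_mM)
})

test_that("cluster means reduce to column means and respect permutations", {
  x <- matrix(rnorm(40), nrow = 8,
              dimnames = list(paste0("c", 1:8), paste0("m", 1:5)))
  expect_equal(unname(cluster_mean_heatmap(x, rep(1, 8))[1, ]),
               unname(colMeans(x)))
  singletons <- cluster_mean_heatmap(x, 1:8)
  expect_equal(unname(singletons), unname(x))
  perm <- sample(8)
  expect_equal(cluster_mean_heatmap(x[perm, ], rep(1:2, 4)[perm]),
               cluster_mean_heatmap(x, rep(1:2, 4)))
  expect_error(cluster_mean_heatmap(x, 1:3), "label")
})
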