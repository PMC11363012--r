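# Shared fixtures and independent oracles for the test suite.

# A minimal three-compound library (iridoid / alkaloid / flavonoid) plus the
# ajmaline internal standard, with well-separated retention times.
tiny_library <- function() {
  compound_library(data.frame(
    name = c("secologanin", "catharanthine", "rutin", "ajmaline"),
    formula = c("C17H24O10", "C21H24N2O2", "C27H30O16", "C20H26N2O2"),
    adduct = c("[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+"),
    charge = 1L,
    expected_rt = c(140, 190, 125, 165),
    class = c("iridoid", "alkaloid", "flavonoid", "internal_standard"),
    quantifiable = c(TRUE, TRUE, TRUE, FALSE),
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

# Small feature table built directly from ion m/z values of a library.
tiny_feature_table <- function(library = tiny_library(), n_cells = 3,
                               areas = NULL) {
  mz <- library_ion_mz(library)
  feats <- data.frame(feature_id = sprintf("F%02d", seq_along(mz)),
                      mz = unname(mz), rt = library$expected_rt,
                      stringsAsFactors = FALSE)
  if (is.null(areas)) {
    areas <- matrix(seq_len(length(mz) * n_cells) * 100,
                    nrow = length(mz),
                    dimnames = list(feats$feature_id,
                                    sprintf("cell%02d", seq_len(n_cells))))
  }
  feature_table(feats, areas)
}

# Independent exhaustive formula-enumeration oracle: builds the full CHNO
# composition grid once with its own mass constants and filters it
# vectorised, sharing no code path with enumerate_formulas().
brute_force_grid <- function(maxC = 25, maxH = 40, maxN = 4, maxO = 12) {
  m <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  g <- expand.grid(C = 0:maxC, H = 0:maxH, N = 0:maxN, O = 0:maxO)
  g$mass <- g$C * m["C"] + g$H * m["H"] + g$N * m["N"] + g$O * m["O"]
  g$rdbe <- g$C - g$H / 2 + g$N / 2 + 1
  g
}

brute_force_enumerate <- function(mz, grid, tol_ppm = 2,
                                  rdbe_range = c(0, 40)) {
  proton <- 1.00782503207 - 5.48579909070e-4
  ion <- grid$mass + proton   # [M+H]+, charge 1
  pe <- (mz - ion) / ion * 1e6
  hit <- which(abs(pe) <= tol_ppm & grid$rdbe >= rdbe_range[1] &
                 grid$rdbe <= rdbe_range[2])
  vapply(hit, function(i) {
    format_formula(c(C = grid$C[i], H = grid$H[i], N = grid$N[i],
                     O = grid$O[i]))
  }, character(1))
}

# CHNO-only bounds for enumerate_formulas matching the oracle grid.
chno_bounds <- function(maxC = 25, maxH = 40, maxN = 4, maxO = 12) {
  data.frame(element = c("C", "H", "N", "O", "P", "S"),
             min = 0L, max = c(maxC, maxH, maxN, maxO, 0L, 0L))
}

# Are two clusterings identical up to a relabelling of the clusters?
same_partition <- function(a, b) {
  all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
}
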