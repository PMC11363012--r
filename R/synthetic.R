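# Synthetic protoplast populations and simulated LC-MS measurements.
#
# The generator encodes the cell-type structure reported for Catharanthus
# roseus leaf, root and petal protoplast populations: a rare alkaloid-rich
# idioblast type (2.5% of cells), a loganic-acid-accumulating IPAP type,
# secologanin-rich epidermal populations (~30% of leaf cells at 50-600 mM),
# anhydrovinblastine restricted to idioblasts (0.3-10 mM), cell diameters
# within 16-45 um, and a 12 uL lysis/extract volume per well.

.profile_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(compound = r[[1]], presence = as.numeric(r[[2]]),
               low = as.numeric(r[[3]]), high = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
  df
}

#' Define a cell type for the population generator
#'
#' @param name Cell-type label.
#' @param proportion Fraction of the population in `[0, 1]`.
#' @param diameter_range Length-2 numeric, min/max protoplast diameter in
#'   micrometres (both > 0, min <= max).
#' @param profile Data frame with columns `compound`, `presence` (probability
#'   in `[0, 1]` that a cell of this type contains the compound), `low`,
#'   `high` (mM bounds of the log-uniform concentration distribution given
#'   presence; 0 < low <= high).
#' @return An object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, proportion, diameter_range, profile) {
  if (proportion < 0 || proportion > 1) stop("proportion must lie in [0, 1]")
  if (length(diameter_range) != 2 || any(diameter_range <= 0) ||
      diameter_range[1] > diameter_range[2]) {
    stop("diameter_range must be positive with min <= max")
  }
  stopifnot(is.data.frame(profile),
            all(c("compound", "presence", "low", "high") %in% names(profile)))
  if (any(profile$presence < 0 | profile$presence > 1)) {
    stop("presence probabilities must lie in [0, 1]")
  }
  if (any(profile$low <= 0) || any(profile$low > profile$high)) {
    stop("concentration bounds must be positive with low <= high")
  }
  structure(list(name = name, proportion = proportion,
                 diameter_range = as.numeric(diameter_range),
                 profile = profile),
            class = "cell_type_spec")
}

#' Define a population configuration
#'
#' @param tissue,cultivar Labels.
#' @param cell_types List of [cell_type_spec()] objects whose proportions sum
#'   to 1 (within 1e-9).
#' @param n_cells Number of cells to generate (>= 0).
#' @param cross_contamination_rate Probability in `[0, 1]` that a picked cell
#'   carries over a small fraction of another cell's content; default 0
#'   (picking is treated as clean).
#' @param seed Optional default seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(tissue, cultivar, cell_types, n_cells,
                              cross_contamination_rate = 0, seed = NULL) {
  stopifnot(length(cell_types) >= 1)
  props <- vapply(cell_types, function(ct) ct$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop("cell-type proportions must sum to 1 (got ", sum(props), ")")
  }
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (cross_contamination_rate < 0 || cross_contamination_rate > 1) {
    stop("cross_contamination_rate must lie in [0, 1]")
  }
  structure(list(tissue = tissue, cultivar = cultivar,
                 cell_types = cell_types, n_cells = as.integer(n_cells),
                 cross_contamination_rate = cross_contamination_rate,
                 seed = seed),
            class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config> ", x$tissue, " / ", x$cultivar, ", ",
      x$n_cells, " cells, ", length(x$cell_types), " cell types\n", sep = "")
  for (ct in x$cell_types) {
    cat(sprintf("  %-24s %5.1f%%  d %g-%g um  %d compounds\n", ct$name,
                100 * ct$proportion, ct$diameter_range[1],
                ct$diameter_range[2], nrow(ct$profile)))
  }
  invisible(x)
}

#' Tissue/cultivar presets for the population generator
#'
#' Returns a [population_config()] whose parameters encode the reported
#' population structure of each tissue: leaf (Sunstorm Apricot, 202 cells)
#' with 2.5% serpentine-fluorescent idioblasts, an IPAP population defined by
#' loganic acid, and two secologanin-rich epidermal populations totalling 30%
#' of cells at 50-600 mM (one co-accumulating the flavonoid mauritianin);
#' root (187 cells) with alkaloid-specialised cells, iridoid+strictosidine
#' cells, strictosidine-only cells and no flavonoids anywhere; and the three
#' petal cultivars (232 cells each). In the Little Bright Eyes (LBE) petal,
#' secologanin occurs only in a cell type that always co-accumulates
#' flavonoids, and total alkaloid levels are the highest of the cultivars.
#' Vinblastine appears only in leaf idioblasts with an overall per-cell
#' probability of about 1/202.
#'
#' Concentration bounds are true in-cell ranges placed slightly inside the
#' reported observed envelopes, so that measured values under the default
#' noise model reproduce the observed ceilings (see the methods vignette).
#'
#' @param tissue_cultivar One of `"leaf-SA"`, `"root-SA"`, `"petal-SA"`,
#'   `"petal-LBE"`, `"petal-ABH"`.
#' @return A `population_config`.
#' @export
build_preset <- function(tissue_cultivar) {
  switch(tissue_cultivar,
    "leaf-SA" = population_config(
      tissue = "leaf", cultivar = "SA", n_cells = 202,
      cell_types = list(
        cell_type_spec("idioblast", 0.025, c(25, 45), .profile_df(
          list("serpentine",          1.0,  2,    50),
          list("catharanthine",       1.0, 10,   300),
          list("vindoline",           1.0, 10,   200),
          list("vindorosine",         1.0,  5,   100),
          list("vindolinine",         1.0,  5,   100),
          list("ajmalicine",          1.0,  1,    20),
          list("anhydrovinblastine",  1.0,  0.3,  10),
          list("vinblastine",         0.2,  0.01,  0.08),
          list("tabersonine",         0.5,  0.5,  10),
          list("strictosidine",       0.5,  1,    20))),
        cell_type_spec("ipap", 0.10, c(20, 40), .profile_df(
          list("loganic acid",        1.0, 10,   400))),
        cell_type_spec("epidermal_flavonoid", 0.15, c(16, 40), .profile_df(
          list("secologanin",         1.0, 50,   300),
          list("mauritianin",         1.0,  1,   100),
          list("catharanthine",       0.3,  0.05,  2),
          list("strictosidine",       0.3,  0.1,   5))),
        cell_type_spec("epidermal_secologanin", 0.15, c(16, 40), .profile_df(
          list("secologanin",         1.0, 50,   600),
          list("catharanthine",       0.3,  0.05,  2),
          list("strictosidine",       0.3,  0.1,   5))),
        cell_type_spec("other", 0.575, c(16, 35), .profile_df(
          list("secologanin",         0.2,  1,    40),
          list("catharanthine",       0.1,  0.05,  1))))),
    "root-SA" = population_config(
      tissue = "root", cultivar = "SA", n_cells = 187,
      cell_types = list(
        cell_type_spec("alkaloid_rich", 0.03, c(20, 40), .profile_df(
          list("catharanthine",       1.0, 10,   300),
          list("tabersonine",         1.0,  1,    50),
          list("serpentine",          0.5,  1,    20),
          list("ajmalicine",          1.0,  1,    30),
          list("strictosidine",       0.3,  1,    10))),
        cell_type_spec("iridoid_strictosidine", 0.15, c(18, 40), .profile_df(
          list("loganic acid",        1.0,  5,   100),
          list("secologanin",         1.0,  1,    30),
          list("strictosidine",       1.0,  1,    50))),
        cell_type_spec("strictosidine_only", 0.12, c(18, 40), .profile_df(
          list("strictosidine",       1.0,  1,    50))),
        cell_type_spec("ground", 0.70, c(16, 38), .profile_df(
          list("catharanthine",       0.1,  0.05,  1),
          list("secologanin",         0.1,  0.5,   5))))),
    "petal-SA" = population_config(
      tissue = "petal", cultivar = "SA", n_cells = 232,
      cell_types = list(
        cell_type_spec("anthocyanin_rich", 0.35, c(16, 35), .profile_df(
          list("rutin",                    1.0,  5, 100),
          list("peonidin-3-O-rutinoside",  1.0,  5, 100),
          list("quercetin",                0.3,  0.5, 10))),
        cell_type_spec("mauritianin_rich", 0.25, c(16, 35), .profile_df(
          list("mauritianin",              1.0, 10, 200))),
        cell_type_spec("alkaloid_rich", 0.05, c(20, 40), .profile_df(
          list("catharanthine",            1.0, 10, 150),
          list("vindoline",                1.0,  5, 100),
          list("serpentine",               1.0,  1,  20),
          list("ajmalicine",               1.0,  1,  20),
          list("vindolinine",              1.0,  2,  50))),
        cell_type_spec("secologanin_rich", 0.08, c(16, 38), .profile_df(
          list("secologanin",              1.0,  5,  50))),
        cell_type_spec("other", 0.27, c(16, 32), .profile_df(
          list("rutin",                    0.3,  0.5,  5))))),
    "petal-LBE" = population_config(
      tissue = "petal", cultivar = "LBE", n_cells = 232,
      cell_types = list(
        cell_type_spec("alkaloid_rich", 0.06, c(20, 42), .profile_df(
          list("catharanthine",            1.0, 20, 200),
          list("vindoline",                1.0, 20, 150),
          list("vindolinine",              1.0, 10, 100),
          list("serpentine",               1.0,  5,  50),
          list("ajmalicine",               1.0,  5,  50),
          list("anhydrovinblastine",       0.5,  0.3,  5))),
        cell_type_spec("seco_flavonoid", 0.20, c(16, 38), .profile_df(
          list("secologanin",              1.0,  5,  60),
          list("mauritianin",              1.0,  5, 100))),
        cell_type_spec("anthocyanin_rich", 0.30, c(16, 35), .profile_df(
          list("rutin",                    1.0,  5, 100),
          list("peonidin-3-O-rutinoside",  1.0,  5, 100))),
        cell_type_spec("other", 0.44, c(16, 32), .profile_df(
          list("rutin",                    0.2,  0.5,  5))))),
    "petal-ABH" = population_config(
      tissue = "petal", cultivar = "ABH", n_cells = 232,
      cell_types = list(
        cell_type_spec("anthocyanin_rich", 0.40, c(16, 35), .profile_df(
          list("rutin",                    1.0,  5, 150),
          list("peonidin-3-O-rutinoside",  1.0,  5, 150),
          list("quercetin",                0.3,  0.5, 10))),
        cell_type_spec("alkaloid_rich", 0.04, c(20, 40), .profile_df(
          list("catharanthine",            1.0, 10, 150),
          list("vindoline",                1.0,  5,  80),
          list("serpentine",               1.0,  1,  20),
          list("ajmalicine",               1.0,  1,  20))),
        cell_type_spec("secologanin_rich", 0.07, c(16, 38), .profile_df(
          list("secologanin",              1.0,  5,  50))),
        cell_type_spec("mauritianin_rich", 0.15, c(16, 35), .profile_df(
          list("mauritianin",              1.0, 10, 200))),
        cell_type_spec("other", 0.34, c(16, 32), .profile_df(
          list("rutin",                    0.3,  0.5,  5))))),
    stop("unknown preset label: '", tissue_cultivar, "' (expected one of ",
         "leaf-SA, root-SA, petal-SA, petal-LBE, petal-ABH)")
  )
}

#' Preset labels understood by [build_preset()]
#' @return Character vector.
#' @export
preset_labels <- function() {
  c("leaf-SA", "root-SA", "petal-SA", "petal-LBE", "petal-ABH")
}

#' Generate a cell population from a configuration
#'
#' Cell types are drawn from the configuration's proportion vector, diameters
#' uniformly within each type's range, and per-compound concentrations by a
#' Bernoulli presence draw followed by a log-uniform draw between the type's
#' bounds. Draws are independent across compounds (between-compound
#' correlation within a cell is not modelled).
#'
#' @param config A `population_config`.
#' @param seed Integer seed; the same config and seed give identical output.
#' @return An object of class `cell_population`: a list with `cells` (data
#'   frame: `cell_id`, `tissue`, `cultivar`, `true_type`, `diameter`) and
#'   `truth` (cells x compounds matrix of true concentrations in mM, 0 when
#'   absent), plus the config and seed.
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  n <- config$n_cells
  type_names <- vapply(config$cell_types, function(ct) ct$name, character(1))
  props <- vapply(config$cell_types, function(ct) ct$proportion, numeric(1))
  compounds <- sort(unique(unlist(
    lapply(config$cell_types, function(ct) ct$profile$compound))))
  truth <- matrix(0, nrow = n, ncol = length(compounds),
                  dimnames = list(NULL, compounds))
  if (n > 0) {
    types <- sample(type_names, n, replace = TRUE, prob = props)
    diam <- numeric(n)
    for (ct in config$cell_types) {
      idx <- which(types == ct$name)
      if (!length(idx)) next
      diam[idx] <- stats::runif(length(idx), ct$diameter_range[1],
                                ct$diameter_range[2])
      for (k in seq_len(nrow(ct$profile))) {
        row <- ct$profile[k, ]
        present <- stats::runif(length(idx)) < row$presence
        if (!any(present)) next
        conc <- exp(stats::runif(sum(present), log(row$low), log(row$high)))
        truth[idx[present], row$compound] <- conc
      }
    }
    cells <- data.frame(
      cell_id = sprintf("%s_%s_c%03d", config$tissue, config$cultivar,
                        seq_len(n)),
      tissue = config$tissue, cultivar = config$cultivar,
      true_type = types, diameter = diam, stringsAsFactors = FALSE)
  } else {
    cells <- data.frame(cell_id = character(0), tissue = character(0),
                        cultivar = character(0), true_type = character(0),
                        diameter = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(truth) <- cells$cell_id
  structure(list(cells = cells, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> ", nrow(x$cells), " cells (", x$config$tissue, "/",
      x$config$cultivar, "), ", ncol(x$truth), " compounds, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Instrument / workflow configuration for simulated measurements
#'
#' @param library Compound library providing the compound set.
#' @param response_factor Named numeric vector, detector response in area
#'   units per mol for each quantifiable compound (all > 0). The default
#'   assigns fixed per-compound factors between 5e14 and 2e15.
#' @param noise_cv Coefficient of variation of the multiplicative (log-normal,
#'   mean-1) measurement noise; default 0.10.
#' @param is_area Nominal internal-standard (ajmaline) peak area per sample.
#' @param is_cv CV of the internal-standard area across samples.
#' @param extract_volume Lysis/extract volume per well in microlitres
#'   (default 12: 6 uL formic acid lysis buffer + 6 uL methanol with the
#'   internal standard).
#' @param qc_aliquot Aliquot taken per well for the pooled QC sample in
#'   microlitres (default 2); must be smaller than `extract_volume`.
#' @param loq_amount Named numeric vector, nominal per-compound limit of
#'   quantification as an amount in mol; default 1.2e-16 (0.12 fmol) for all.
#' @param mz_sigma_ppm Standard deviation of the per-feature m/z error (ppm).
#' @param rt_sigma Standard deviation of the per-feature RT error (seconds).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(library = cr_compound_library(),
                              response_factor = NULL,
                              noise_cv = 0.10, is_area = 1e6, is_cv = 0.05,
                              extract_volume = 12, qc_aliquot = 2,
                              loq_amount = NULL,
                              mz_sigma_ppm = 0.3, rt_sigma = 1.5) {
  library <- validate_compound_library(library)
  quant <- library$name[library$quantifiable]
  if (is.null(response_factor)) {
    # fixed spread of response factors, deterministic in library order
    rf <- 5e14 * 4^(((seq_along(quant) - 1) %% 5) / 4)
    response_factor <- stats::setNames(rf, quant)
  }
  if (is.null(loq_amount)) {
    loq_amount <- stats::setNames(rep(1.2e-16, length(quant)), quant)
  }
  missing <- setdiff(quant, names(response_factor))
  if (length(missing)) {
    stop("response_factor missing compound(s): ", paste(missing, collapse = ", "))
  }
  if (any(response_factor <= 0)) stop("response factors must be > 0")
  if (noise_cv < 0 || is_cv < 0) stop("cvs must be >= 0")
  if (!(extract_volume > qc_aliquot && qc_aliquot >= 0)) {
    stop("need extract_volume > qc_aliquot >= 0")
  }
  structure(list(library = library, response_factor = response_factor,
                 noise_cv = noise_cv, is_area = is_area, is_cv = is_cv,
                 extract_volume = extract_volume, qc_aliquot = qc_aliquot,
                 loq_amount = loq_amount, mz_sigma_ppm = mz_sigma_ppm,
                 rt_sigma = rt_sigma),
            class = "instrument_config")
}

# mean-1 log-normal multiplicative noise factors; exact 1 when cv = 0
.lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the LC-MS measurement of a cell population
#'
#' For each cell, the true in-cell amount of each compound (concentration x
#' spherical cell volume) is released into the well extract and produces a
#' peak area `response_factor x amount x noise`, with mean-1 log-normal
#' multiplicative noise. The internal-standard feature is present in every
#' sample. Amounts below the nominal LOQ still produce signal; censoring is a
#' downstream quantification decision. With a positive cross-contamination
#' rate, an affected cell additionally receives 2% of a random other cell's
#' amounts.
#'
#' @param population A `cell_population`.
#' @param instrument An `instrument_config`.
#' @param seed Integer seed.
#' @return List with `table` (a `feature_table`, one feature per library
#'   compound plus the internal standard, one sample per cell) and `metadata`
#'   (a `cell_metadata` data frame).
#' @export
simulate_measurement <- function(population, instrument, seed) {
  stopifnot(inherits(population, "cell_population"),
            inherits(instrument, "instrument_config"))
  set.seed(as.integer(seed))
  lib <- instrument$library
  cells <- population$cells
  if (any(cells$diameter <= 0)) stop("nonpositive cell diameter")
  if (any(population$truth < 0)) stop("negative true concentration")
  n <- nrow(cells)
  quant <- lib$name[lib$quantifiable]
  unknown <- setdiff(colnames(population$truth), quant)
  if (length(unknown)) {
    stop("compound(s) in cell profiles missing from the library: ",
         paste(unknown, collapse = ", "))
  }

  vol_pl <- cell_volume_from_diameter(cells$diameter)       # pL
  # amount (mol) = conc (mM) * volume (pL) * 1e-15
  amount <- matrix(0, nrow = n, ncol = length(quant),
                   dimnames = list(cells$cell_id, quant))
  present <- intersect(colnames(population$truth), quant)
  if (n > 0 && length(present)) {
    amount[, present] <- population$truth[, present, drop = FALSE] * vol_pl * 1e-15
  }
  rate <- population$config$cross_contamination_rate
  if (rate > 0 && n > 1) {
    hit <- which(stats::runif(n) < rate)
    for (i in hit) {
      donor <- sample(setdiff(seq_len(n), i), 1)
      amount[i, ] <- amount[i, ] + 0.02 * amount[donor, ]
    }
  }

  rf <- instrument$response_factor[quant]
  areas <- t(t(amount) * rf)
  if (n > 0) {
    areas <- areas * matrix(.lognormal_factors(length(areas), instrument$noise_cv),
                            nrow = n)
  }
  is_row <- .lognormal_factors(n, instrument$is_cv) * instrument$is_area
  areas <- rbind(t(areas), ajmaline_IS = is_row)

  lib_idx <- c(match(quant, lib$name), which(lib$is_internal_standard)[1])
  true_mz <- vapply(lib_idx, function(i) ion_mz(lib$formula[i], lib$adduct[i]),
                    numeric(1))
  nf <- length(lib_idx)
  feats <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = true_mz * (1 + stats::rnorm(nf, 0, instrument$mz_sigma_ppm) * 1e-6),
    rt = pmax(0, lib$expected_rt[lib_idx] + stats::rnorm(nf, 0, instrument$rt_sigma)),
    stringsAsFactors = FALSE)
  rownames(areas) <- feats$feature_id
  colnames(areas) <- cells$cell_id
  table <- feature_table(feats, areas, seed = as.integer(seed))

  wells <- sprintf("P%d-%s%d", (seq_len(max(n, 1)) - 1) %/% 96 + 1,
                   LETTERS[((seq_len(max(n, 1)) - 1) %/% 12) %% 8 + 1],
                   (seq_len(max(n, 1)) - 1) %% 12 + 1)
  antho <- lib$name[lib$class == "anthocyanin" & lib$quantifiable]
  meta <- cell_metadata(data.frame(
    cell_id = cells$cell_id, well = wells[seq_len(n)],
    diameter = cells$diameter,
    fluorescent = if (n > 0 && "serpentine" %in% colnames(population$truth))
      population$truth[, "serpentine"] > 0 else logical(n),
    colored = if (n > 0 && length(antho) && any(antho %in% colnames(population$truth)))
      rowSums(population$truth[, intersect(antho, colnames(population$truth)),
                               drop = FALSE]) > 0 else logical(n),
    tissue = cells$tissue, stringsAsFactors = FALSE))
  attr(meta, "seed") <- as.integer(seed)
  list(table = table, metadata = meta)
}

#' Default calibration levels
#'
#' Seven extract concentrations log-spaced from 1e-5 to 10 micromolar. With
#' the default 12 uL extract volume the lowest level corresponds to 0.12 fmol
#' in the well, matching the nominal instrument LOQ.
#'
#' @return Numeric vector of concentrations in micromolar (pmol/uL).
#' @export
default_calibration_levels <- function() 10^seq(-5, 1)

#' Simulate an external calibration series
#'
#' One measurement per compound, level and replicate, generated with the same
#' response model as [simulate_measurement()]: a standard at extract
#' concentration `level` (micromolar) in an `extract_volume` uL well holds
#' `level * extract_volume` pmol and yields area
#' `response_factor x amount x noise`.
#'
#' @param instrument An `instrument_config`.
#' @param levels Strictly positive, sorted concentrations in micromolar.
#' @param replicates Replicates per level (default 3).
#' @param seed Integer seed.
#' @param compounds Compound names to calibrate; default every quantifiable
#'   library compound.
#' @return Long data frame `compound`, `level`, `replicate`, `area` with the
#'   seed stored as an attribute.
#' @export
simulate_calibration_series <- function(instrument,
                                        levels = default_calibration_levels(),
                                        replicates = 3, seed = 1,
                                        compounds = NULL) {
  stopifnot(inherits(instrument, "instrument_config"))
  if (!length(levels)) stop("calibration level list must be nonempty")
  if (any(levels <= 0)) stop("calibration levels must be strictly positive")
  if (is.unsorted(levels)) stop("calibration levels must be sorted")
  set.seed(as.integer(seed))
  lib <- instrument$library
  if (is.null(compounds)) compounds <- lib$name[lib$quantifiable]
  missing <- setdiff(compounds, names(instrument$response_factor))
  if (length(missing)) {
    stop("no response factor for compound(s): ", paste(missing, collapse = ", "))
  }
  grid <- expand.grid(replicate = seq_len(replicates), level = levels,
                      compound = compounds, stringsAsFactors = FALSE)
  amount_mol <- grid$level * instrument$extract_volume * 1e-12  # uM * uL = pmol
  grid$area <- instrument$response_factor[grid$compound] * amount_mol *
    .lognormal_factors(nrow(grid), instrument$noise_cv)
  out <- grid[, c("compound", "level", "replicate", "area")]
  attr(out, "seed") <- as.integer(seed)
  out
}

#' A noiseless instrument configuration
#'
#' Convenience wrapper setting every noise term to zero; useful for
#' round-trip verification of the quantification chain.
#'
#' @param ... Passed to [instrument_config()].
#' @return An `instrument_config`.
#' @export
noiseless_instrument <- function(...) {
  instrument_config(noise_cv = 0, is_cv = 0, mz_sigma_ppm = 0, rt_sigma = 0, ...)
}
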