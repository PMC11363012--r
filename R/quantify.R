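# Absolute quantification: external calibration with a back-calculation
# accuracy filter, internal-standard normalization, sphere volumes from
# imaged diameters, and area -> in-cell molar concentration conversion.
#
# Unit conventions: calibration levels and extract concentrations in
# micromolar (pmol/uL); well amounts in mol; cell volumes in pL; in-cell
# concentrations in mM. amount (mol) = conc (mM) x volume (pL) x 1e-15.

#' Fit an external calibration curve
#'
#' Weighted least-squares line `area = intercept + slope * level`, followed by
#' a back-calculation accuracy filter: any level whose back-calculated
#' concentration (from its mean area) deviates from nominal by more than
#' `accuracy_tol` (default 20%) is excluded and the line refit, iterating to
#' convergence. The linear range is the span of retained levels and the LOQ
#' is the lowest retained level, expressed as an amount in the
#' `extract_volume` uL well.
#'
#' @param levels Concentrations (micromolar), at least 3 distinct values;
#'   replicates allowed.
#' @param areas Peak areas (>= 0), same length as `levels`.
#' @param weighting `"1/x2"` (default), `"1/x"`, or `"none"`. With
#'   calibration series spanning several orders of magnitude, `1/x^2`
#'   equalises relative error across levels; `1/x` lets the top levels
#'   dominate the fit and destabilises the intercept at the bottom of the
#'   range.
#' @param compound Optional compound name stored on the curve.
#' @param extract_volume Extract volume in microlitres used to express the
#'   LOQ as an amount (default 12).
#' @param accuracy_tol Relative back-calculation tolerance (default 0.2).
#' @return An object of class `calibration_curve`: list with `compound`,
#'   `slope` (area per micromolar), `intercept`, `weighting`, `linear_range`
#'   (micromolar), `loq_level` (micromolar), `loq` (amount, mol),
#'   `r_squared`, `n_levels`.
#' @export
fit_calibration <- function(levels, areas, weighting = c("1/x2", "1/x", "none"),
                            compound = NA_character_, extract_volume = 12,
                            accuracy_tol = 0.2) {
  weighting <- match.arg(weighting)
  stopifnot(length(levels) == length(areas))
  if (any(levels <= 0)) stop("calibration levels must be > 0")
  if (any(areas < 0)) stop("calibration areas must be >= 0")
  retained <- sort(unique(levels))
  if (length(retained) < 3) stop("calibration failed: fewer than 3 levels")

  fit_once <- function(keep_levels) {
    sel <- levels %in% keep_levels
    w <- switch(weighting, "none" = rep(1, sum(sel)),
                "1/x" = 1 / levels[sel], "1/x2" = 1 / levels[sel]^2)
    fit <- stats::lm(areas[sel] ~ levels[sel], weights = w)
    # weighted R^2 computed directly: summary.lm warns on noiseless fits
    res <- stats::residuals(fit)
    ybar <- sum(w * areas[sel]) / sum(w)
    sst <- sum(w * (areas[sel] - ybar)^2)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = if (sst > 0) 1 - sum(w * res^2) / sst else NA_real_)
  }

  repeat {
    f <- fit_once(retained)
    if (!is.finite(f$slope) || f$slope <= 0) {
      stop("calibration failed: nonpositive or undefined slope",
           if (!is.na(compound)) paste0(" for ", compound))
    }
    back <- vapply(retained, function(l) {
      (mean(areas[levels == l]) - f$intercept) / f$slope
    }, numeric(1))
    relerr <- abs(back - retained) / retained
    relerr[!is.finite(relerr)] <- Inf
    if (all(relerr <= accuracy_tol)) break
    # drop the single worst level, then refit: removing everything failing
    # at once would let one distorted level (e.g. a saturated top point)
    # drag otherwise-linear levels out with it
    retained <- retained[-which.max(relerr)]
    if (length(retained) < 3) {
      stop("calibration failed: fewer than 3 levels pass the ",
           100 * accuracy_tol, "% back-calculation filter",
           if (!is.na(compound)) paste0(" for ", compound))
    }
  }
  structure(list(compound = compound, slope = f$slope, intercept = f$intercept,
                 weighting = weighting,
                 linear_range = range(retained),
                 loq_level = min(retained),
                 loq = min(retained) * extract_volume * 1e-12,
                 r_squared = f$r2, n_levels = length(retained)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4g, intercept %.4g, R2 %.6f, range %.3g-%.3g uM, LOQ %.3g mol\n",
              x$compound, x$slope, x$intercept, x$r_squared,
              x$linear_range[1], x$linear_range[2], x$loq))
  invisible(x)
}

#' Fit calibration curves for every compound in a series
#'
#' @param series Long data frame `compound`, `level`, `area` (see
#'   [simulate_calibration_series()]).
#' @param ... Passed to [fit_calibration()].
#' @return Named list of `calibration_curve` objects.
#' @export
fit_calibration_table <- function(series, ...) {
  stopifnot(all(c("compound", "level", "area") %in% names(series)))
  out <- lapply(split(series, series$compound), function(d) {
    fit_calibration(d$level, d$area, compound = d$compound[1], ...)
  })
  out[unique(series$compound)]
}

#' Normalize peak areas to the internal standard
#'
#' Each sample's areas are scaled by `median(IS area) / (that sample's IS
#' area)`, correcting per-sample response drift. Samples whose IS area is
#' zero or missing are excluded with a warning and listed in the
#' `excluded_samples` attribute.
#'
#' @param table A `feature_table`.
#' @param is_feature_id Feature id of the internal-standard feature.
#' @return The corrected `feature_table`.
#' @export
normalize_internal_standard <- function(table, is_feature_id) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_feature_id %in% table$features$feature_id) {
    stop("internal-standard feature '", is_feature_id, "' not in table")
  }
  is_area <- table$areas[is_feature_id, ]
  bad <- !is.finite(is_area) | is_area <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " sample(s) with zero/missing internal-",
            "standard area: ", paste(table$samples[bad], collapse = ", "))
  }
  keep <- which(!bad)
  if (!length(keep)) stop("no sample has a positive internal-standard area")
  med <- stats::median(is_area[keep])
  areas <- sweep(table$areas[, keep, drop = FALSE], 2,
                 med / is_area[keep], "*")
  out <- feature_table(table$features, areas, seed = table$seed)
  attr(out, "excluded_samples") <- table$samples[bad]
  out
}

#' Cell volume from imaged diameter
#'
#' Protoplasts are treated as spheres: `V = (pi/6) d^3`, reported in
#' picolitres (1 pL = 1000 um^3).
#'
#' @param diameter Diameter(s) in micrometres, > 0.
#' @return Volume(s) in pL.
#' @examples
#' cell_volume_from_diameter(20)  # 4.18879 pL
#' @export
cell_volume_from_diameter <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  (pi / 6) * diameter^3 / 1000
}

#' Convert a peak area to an amount in the cell extract
#'
#' Inverts the calibration line: extract concentration
#' `(area - intercept) / slope` (micromolar), then amount
#' `concentration x extract_volume` (pmol -> mol). The pooled-QC aliquot does
#' not change the extract concentration (an intensive quantity), so the full
#' extract volume represents the cell's content. Areas at or below the
#' intercept are flagged `below_loq` rather than producing negative amounts;
#' amounts under the curve LOQ are `below_loq`; concentrations above the
#' linear range are flagged `above_range` (value still reported).
#'
#' @param area Peak area(s).
#' @param curve A `calibration_curve`.
#' @param extract_volume Extract volume in microlitres (default 12).
#' @return List with `amount` (mol, NA where below LOQ) and `flag`
#'   (`"quantified"`, `"below_loq"`, `"above_range"`).
#' @export
area_to_cell_amount <- function(area, curve, extract_volume = 12) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (extract_volume <= 0) stop("extract_volume must be > 0")
  conc <- (area - curve$intercept) / curve$slope          # uM
  amount <- conc * extract_volume * 1e-12                 # mol
  flag <- rep("quantified", length(area))
  flag[area <= curve$intercept | amount < curve$loq * (1 - 1e-12)] <- "below_loq"
  flag[flag == "quantified" & conc > curve$linear_range[2] * (1 + 1e-12)] <-
    "above_range"
  amount[flag == "below_loq"] <- NA_real_
  list(amount = amount, flag = flag)
}

#' In-cell molar concentration from amount and cell volume
#'
#' @param amount Amount(s) in mol, >= 0.
#' @param volume Cell volume(s) in pL, > 0.
#' @return Concentration(s) in mM.
#' @examples
#' cell_concentration(1e-12, cell_volume_from_diameter(20))  # 238.7 mM
#' @export
cell_concentration <- function(amount, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  if (any(amount < 0, na.rm = TRUE)) stop("amount must be >= 0")
  amount * 1e15 / volume
}

#' Quantify every cell and compound
#'
#' Composes the quantification chain: optional internal-standard
#' normalization, calibration-based area-to-amount conversion, spherical cell
#' volume from the imaged diameter, and amount-to-concentration conversion.
#' Entry status is `absent` when no signal was detected for the compound's
#' feature in that cell, `below_loq`/`above_range` from the calibration
#' flags, otherwise `quantified`.
#'
#' @param table A `feature_table` whose samples are cell ids.
#' @param metadata A `cell_metadata` data frame covering every sample.
#' @param curves Named list of `calibration_curve`s, one per quantifiable
#'   compound in `library`.
#' @param assignments Feature-to-compound assignments from
#'   [match_known_compounds()].
#' @param library A `compound_library`.
#' @param extract_volume Extract volume in microlitres (default 12).
#' @param normalize_is Apply internal-standard normalization first (default
#'   TRUE; requires an assigned internal-standard feature).
#' @return An object of class `quant_matrix`: list with `concentration`
#'   (cells x compounds, mM; NA where not quantified), `status` (character
#'   matrix of flags), `amount` (mol), `volume` (pL per cell), `metadata`,
#'   `library`.
#' @export
quantify_cells <- function(table, metadata, curves, assignments, library,
                           extract_volume = 12, normalize_is = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- cell_metadata(as.data.frame(metadata))
  library <- validate_compound_library(library)
  quant <- library$name[library$quantifiable]
  missing_curve <- setdiff(quant, names(curves))
  if (length(missing_curve)) {
    stop("missing calibration curve for quantifiable compound(s): ",
         paste(missing_curve, collapse = ", "))
  }
  if (normalize_is) {
    is_name <- library$name[library$is_internal_standard][1]
    is_feat <- assignments$feature_id[assignments$compound == is_name]
    if (!length(is_feat)) {
      stop("internal-standard feature (", is_name, ") not found among ",
           "assignments; set normalize_is = FALSE or assign it")
    }
    table <- normalize_internal_standard(table, is_feat[1])
  }
  cells <- table$samples
  mrow <- match(cells, metadata$cell_id)
  if (anyNA(mrow)) {
    stop("metadata missing cell(s): ",
         paste(cells[is.na(mrow)], collapse = ", "))
  }
  vol <- cell_volume_from_diameter(metadata$diameter[mrow])

  conc <- matrix(NA_real_, nrow = length(cells), ncol = length(quant),
                 dimnames = list(cells, quant))
  amt <- conc
  status <- matrix("absent", nrow = length(cells), ncol = length(quant),
                   dimnames = list(cells, quant))
  for (cmp in quant) {
    feat <- assignments$feature_id[assignments$compound == cmp]
    if (!length(feat) || !feat[1] %in% table$features$feature_id) next
    area <- table$areas[feat[1], ]
    detected <- area > 0
    if (!any(detected)) next
    res <- area_to_cell_amount(area[detected], curves[[cmp]], extract_volume)
    status[detected, cmp] <- res$flag
    amt[detected, cmp] <- res$amount
    cc <- cell_concentration(ifelse(is.na(res$amount), 0, res$amount),
                             vol[detected])
    cc[is.na(res$amount)] <- NA_real_
    conc[detected, cmp] <- cc
  }
  structure(list(concentration = conc, status = status, amount = amt,
                 volume = stats::setNames(vol, cells),
                 metadata = metadata[mrow, , drop = FALSE], library = library),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("<quant_matrix> ", nrow(x$concentration), " cells x ",
      ncol(x$concentration), " compounds; ",
      sum(x$status == "quantified"), " quantified entries\n", sep = "")
  invisible(x)
}

#' Write a quant matrix as CSV (paired value/status columns)
#'
#' @param quant A `quant_matrix`.
#' @param path File path.
#' @export
write_quant_matrix <- function(quant, path) {
  stopifnot(inherits(quant, "quant_matrix"))
  cmp <- colnames(quant$concentration)
  df <- data.frame(cell_id = rownames(quant$concentration),
                   volume_pl = unname(quant$volume),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (c0 in cmp) {
    df[[paste0(c0, "_mM")]] <- quant$concentration[, c0]
    df[[paste0(c0, "_status")]] <- quant$status[, c0]
  }
  .write_csv_with_seed(df, path)
  invisible(path)
}

#' Maximum solubility of a monoprotic base
#'
#' `S = S0 * (1 + 10^(pKa - pH))`: the intrinsic (neutral-form) solubility
#' plus the protonated fraction it supports at the given pH. Used as a
#' plausibility bound for quantified alkaloid concentrations (e.g.
#' catharanthine at vacuolar pH 5).
#'
#' @param intrinsic_solubility `S0` in molar, > 0 (0 allowed, giving 0).
#' @param pKa,pH Positive numerics.
#' @return Maximum total solubility in molar.
#' @export
max_base_solubility <- function(intrinsic_solubility, pKa, pH) {
  if (any(intrinsic_solubility < 0) || any(pKa <= 0) || any(pH <= 0)) {
    stop("inputs must be positive (intrinsic solubility >= 0)")
  }
  intrinsic_solubility * (1 + 10^(pKa - pH))
}

#' Flag quantified concentrations exceeding a solubility bound
#'
#' @param quant A `quant_matrix`.
#' @param solubility_params Data frame `compound`, `s0` (molar), `pka`.
#' @param pH Ambient pH (default 5, the expected vacuolar pH).
#' @return Logical matrix (cells x listed compounds): TRUE where the
#'   quantified concentration exceeds the solubility limit. Exceeding entries
#'   are flagged, never clipped.
#' @export
flag_supersaturated <- function(quant, solubility_params, pH = 5) {
  stopifnot(inherits(quant, "quant_matrix"),
            all(c("compound", "s0", "pka") %in% names(solubility_params)))
  cmp <- intersect(solubility_params$compound, colnames(quant$concentration))
  out <- matrix(FALSE, nrow = nrow(quant$concentration), ncol = length(cmp),
                dimnames = list(rownames(quant$concentration), cmp))
  for (c0 in cmp) {
    i <- match(c0, solubility_params$compound)
    lim_mm <- 1e3 * max_base_solubility(solubility_params$s0[i],
                                        solubility_params$pka[i], pH)
    v <- quant$concentration[, c0]
    out[, c0] <- !is.na(v) & quant$status[, c0] == "quantified" & v > lim_mm
  }
  out
}
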