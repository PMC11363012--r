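# Accurate-mass arithmetic: monoisotopic masses, adduct/charge ion m/z,
# ppm errors, RDBE, and bounded molecular-formula enumeration.

# Most-abundant-isotope masses (Da), IUPAC/CODATA values.
.ISOTOPE_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809
)

.ELECTRON_MASS <- 5.48579909070e-4

# Supported positive-mode adducts. `shift` is the mass added to the neutral
# monoisotopic mass M before dividing by the charge; it already subtracts
# `charge` electron masses, so ion_mz = (M + shift) / charge.
.ADDUCTS <- data.frame(
  adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+2H]2+", "[M]+"),
  shift = c(
    1.00782503207 - 5.48579909070e-4,
    14.0030740048 + 4 * 1.00782503207 - 5.48579909070e-4,
    22.9897692809 - 5.48579909070e-4,
    2 * (1.00782503207 - 5.48579909070e-4),
    -5.48579909070e-4
  ),
  charge = c(1L, 1L, 1L, 2L, 1L),
  stringsAsFactors = FALSE
)

#' Supported adducts
#'
#' Positive-mode adducts handled by [ion_mz()] and [enumerate_formulas()],
#' with their mass shifts (relative to the neutral monoisotopic mass, electron
#' masses already removed) and charges.
#'
#' @return A data frame with columns `adduct`, `shift` (Da) and `charge`.
#' @export
supported_adducts <- function() .ADDUCTS

#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as `"C21H24N2O2"` into a named integer
#' vector of element counts.
#'
#' @param formula Character scalar, e.g. `"C17H24O10"`. An empty string is the
#'   empty formula.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula string: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(elems, names(.ISOTOPE_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  stats::setNames(as.integer(out), names(out))
}

#' Format element counts as a Hill-notation formula
#'
#' @param counts Named integer vector of element counts (zeros are dropped).
#' @return Character scalar: carbon first, hydrogen second, remaining elements
#'   alphabetical; counts of one are implicit.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  nm <- names(counts)
  ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sums the masses of the most abundant isotope of each element.
#'
#' @param formula Formula string (see [parse_formula()]) or a named integer
#'   vector of element counts.
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C21H24N2O2")  # catharanthine, 336.1838
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (!length(counts)) return(0)
  if (any(counts < 0)) stop("element counts must be nonnegative")
  unknown <- setdiff(names(counts), names(.ISOTOPE_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ISOTOPE_MASS[names(counts)] * counts)
}

#' Ion m/z for a neutral formula and adduct
#'
#' Computes `(M + adduct shift) / charge` where the shift accounts for the
#' added atoms minus the charge-carrying electrons (the electron mass matters
#' at the fourth decimal).
#'
#' @param formula Neutral formula string or named count vector. For
#'   permanently charged species handled as `[M]+` (for example anthocyanin
#'   flavylium cations), `formula` is the composition of the cation itself.
#' @param adduct One of `supported_adducts()$adduct`.
#' @param charge Optional integer; if given it must equal the adduct's charge.
#' @return Ion m/z in Th.
#' @examples
#' ion_mz("C21H24N2O2", "[M+H]+")        # 337.19
#' ion_mz("C16H24O10", "[M+NH4]+")       # 394.17
#' ion_mz("C46H56N4O8", "[M+2H]2+")      # 397.21
#' @export
ion_mz <- function(formula, adduct, charge = NULL) {
  i <- match(adduct, .ADDUCTS$adduct)
  if (is.na(i)) stop("unsupported adduct label: '", adduct, "'")
  if (!is.null(charge) && charge != .ADDUCTS$charge[i]) {
    stop("charge ", charge, " inconsistent with adduct ", adduct)
  }
  (monoisotopic_mass(formula) + .ADDUCTS$shift[i]) / .ADDUCTS$charge[i]
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1, a chemical-plausibility filter for formula
#' candidates.
#'
#' @param formula Formula string or named count vector.
#' @return Numeric RDBE (may be half-integral for odd-electron compositions).
#' @export
rdbe <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  g("C") - g("H") / 2 + g("N") / 2 + 1
}

#' Default element bounds for formula enumeration
#'
#' C 0-60, H 0-100, N 0-6, O 0-20, P 0-2, S 0-2: wide enough for iridoid,
#' flavonoid, anthocyanin and monoterpene indole alkaloid chemistry while
#' keeping the search space tractable.
#'
#' @return Data frame with columns `element`, `min`, `max`.
#' @export
default_element_bounds <- function() {
  data.frame(
    element = c("C", "H", "N", "O", "P", "S"),
    min = 0L,
    max = c(60L, 100L, 6L, 20L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

.check_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("element", "min", "max") %in% names(bounds)))
  if (any(bounds$min < 0) || any(bounds$min > bounds$max)) {
    stop("element bounds must satisfy 0 <= min <= max")
  }
  missing <- setdiff(c("C", "H", "N", "O", "P", "S"), bounds$element)
  if (length(missing)) {
    bounds <- rbind(bounds, data.frame(element = missing, min = 0L, max = 0L))
  }
  rownames(bounds) <- bounds$element
  bounds
}

#' Enumerate molecular formulas matching an observed m/z
#'
#' Finds every CHNOPS composition within the element bounds whose ion m/z for
#' at least one adduct lies within `tol_ppm` of the query, and whose RDBE lies
#' within `rdbe_range`. Candidates are sorted by absolute ppm error, ties
#' broken by lower RDBE and then lexicographic formula, so output order is
#' deterministic.
#'
#' @param mz Observed m/z (> 0).
#' @param adducts Character vector of adduct labels to consider (nonempty).
#' @param tol_ppm Match tolerance in ppm (> 0); the filter applies to the
#'   absolute value of the signed error.
#' @param bounds Element bounds as from [default_element_bounds()].
#' @param rdbe_range Length-2 numeric, inclusive RDBE window.
#' @return Data frame with columns `formula`, `adduct`, `theoretical_mz`,
#'   `ppm_error`, `rdbe`; zero rows when nothing matches.
#' @export
enumerate_formulas <- function(mz, adducts = "[M+H]+", tol_ppm = 2,
                               bounds = default_element_bounds(),
                               rdbe_range = c(0, 40)) {
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0) stop("mz must be > 0")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (!length(adducts)) stop("adduct set must be nonempty")
  bad <- setdiff(adducts, .ADDUCTS$adduct)
  if (length(bad)) stop("unsupported adduct label: ", paste(bad, collapse = ", "))
  b <- .check_bounds(bounds)
  lo <- function(el) b[el, "min"]; hi <- function(el) b[el, "max"]
  mH <- .ISOTOPE_MASS[["H"]]

  rows <- vector("list", 64L); nr <- 0L
  for (ad in adducts) {
    i <- match(ad, .ADDUCTS$adduct)
    z <- .ADDUCTS$charge[i]
    # neutral-mass window implied by the ppm window on the ion m/z
    m_lo <- mz * (1 - tol_ppm * 1e-6) * z - .ADDUCTS$shift[i]
    m_hi <- mz * (1 + tol_ppm * 1e-6) * z - .ADDUCTS$shift[i]
    if (m_hi <= 0) next
    for (nC in lo("C"):hi("C")) {
      mc <- nC * 12
      if (mc > m_hi) break
      for (nN in lo("N"):hi("N")) {
        mn <- mc + nN * .ISOTOPE_MASS[["N"]]
        if (mn > m_hi) break
        for (nO in lo("O"):hi("O")) {
          mo <- mn + nO * .ISOTOPE_MASS[["O"]]
          if (mo > m_hi) break
          for (nP in lo("P"):hi("P")) {
            mp <- mo + nP * .ISOTOPE_MASS[["P"]]
            if (mp > m_hi) break
            for (nS in lo("S"):hi("S")) {
              ms <- mp + nS * .ISOTOPE_MASS[["S"]]
              if (ms > m_hi) break
              # remaining mass fixes the hydrogen count up to the tolerance
              h_min <- max(lo("H"), ceiling((m_lo - ms) / mH - 1e-9))
              h_max <- min(hi("H"), floor((m_hi - ms) / mH + 1e-9))
              if (h_max < h_min) next
              for (nH in h_min:h_max) {
                rd <- nC - nH / 2 + nN / 2 + 1
                if (rd < rdbe_range[1] || rd > rdbe_range[2]) next
                M <- ms + nH * mH
                tmz <- (M + .ADDUCTS$shift[i]) / z
                pe <- (mz - tmz) / tmz * 1e6
                if (abs(pe) > tol_ppm) next
                counts <- c(C = nC, H = nH, N = nN, O = nO, P = nP, S = nS)
                nr <- nr + 1L
                if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
                rows[[nr]] <- data.frame(
                  formula = format_formula(counts), adduct = ad,
                  theoretical_mz = tmz, ppm_error = pe, rdbe = rd,
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
  }
  if (nr == 0L) {
    return(data.frame(formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      rdbe = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  out <- out[order(abs(out$ppm_error), out$rdbe, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match features against a compound library
#'
#' A feature is assigned to a library compound when its m/z lies within
#' `tol_ppm` of the compound's ion m/z (for the compound's stated adduct) and
#' its retention time lies within `rt_window` of the compound's expected RT.
#' Isobaric compounds (for example catharanthine, tabersonine and vindolinine,
#' all C21H24N2O2) are disambiguated by retention time alone: among compounds
#' passing both filters the smallest absolute RT difference wins, with the
#' smaller absolute ppm error as a final tie-break.
#'
#' @param table A `feature_table` (see [feature_table()]).
#' @param library Compound library data frame (see [compound_library()]);
#'   compound names must be unique.
#' @param tol_ppm Mass tolerance in ppm.
#' @param rt_window Retention-time window in seconds.
#' @return Data frame with one row per assigned feature: `feature_id`,
#'   `compound`, `ppm_error`, `rt_diff`. Unassigned features are omitted.
#' @export
match_known_compounds <- function(table, library, tol_ppm = 2, rt_window = 10) {
  stopifnot(inherits(table, "feature_table"))
  library <- validate_compound_library(library)
  if (anyDuplicated(library$name)) {
    stop("duplicate compound names in library: ",
         paste(unique(library$name[duplicated(library$name)]), collapse = ", "))
  }
  lib_mz <- vapply(seq_len(nrow(library)), function(i) {
    ion_mz(library$formula[i], library$adduct[i])
  }, numeric(1))
  feats <- table$features
  out <- vector("list", nrow(feats)); nr <- 0L
  for (j in seq_len(nrow(feats))) {
    pe <- ppm_error(feats$mz[j], lib_mz)
    dt <- feats$rt[j] - library$expected_rt
    ok <- which(abs(pe) <= tol_ppm & abs(dt) <= rt_window)
    if (!length(ok)) next
    best <- ok[order(abs(dt[ok]), abs(pe[ok]))][1]
    nr <- nr + 1L
    out[[nr]] <- data.frame(
      feature_id = feats$feature_id[j], compound = library$name[best],
      ppm_error = pe[best], rt_diff = dt[best], stringsAsFactors = FALSE)
  }
  if (nr == 0L) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      ppm_error = numeric(0), rt_diff = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(nr)])
  rownames(res) <- NULL
  res
}
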