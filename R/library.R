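# Compound library: identities, adducts, charges, expected retention times
# and compound classes of the quantifiable metabolites, plus the ajmaline
# internal standard.

.COMPOUND_CLASSES <- c("iridoid", "alkaloid", "flavonoid", "anthocyanin")

#' Construct / validate a compound library
#'
#' @param df Data frame with columns `name`, `formula` (neutral composition;
#'   for permanently charged anthocyanins, the cation composition with adduct
#'   `[M]+`), `adduct`, `charge`, `expected_rt` (seconds), `class`,
#'   `quantifiable` (logical), and optionally `is_internal_standard`.
#' @return The validated data frame with class `compound_library`.
#' @export
compound_library <- function(df) validate_compound_library(df)

#' @rdname compound_library
#' @export
validate_compound_library <- function(df) {
  req <- c("name", "formula", "adduct", "charge", "expected_rt", "class",
           "quantifiable")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("compound library missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"is_internal_standard" %in% names(df)) df$is_internal_standard <- FALSE
  if (any(!nzchar(df$formula))) stop("compound library: empty formula")
  if (any(df$charge < 1)) stop("compound library: charge must be >= 1")
  bad <- setdiff(df$adduct, supported_adducts()$adduct)
  if (length(bad)) stop("unsupported adduct label: ", paste(bad, collapse = ", "))
  badc <- setdiff(df$class, c(.COMPOUND_CLASSES, "internal_standard"))
  if (length(badc)) stop("unknown compound class: ", paste(badc, collapse = ", "))
  for (i in seq_len(nrow(df))) parse_formula(df$formula[i])  # errors on bad symbols
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Reference compound library for Catharanthus roseus single-cell work
#'
#' Sixteen quantifiable natural products across the four compound classes
#' (iridoids, monoterpene indole alkaloids, flavonoids, anthocyanins) plus
#' the ajmaline internal standard. Formulas and adducts reproduce the
#' reported ion m/z values for the marker metabolites (e.g. catharanthine
#' [M+H]+ 337.19, loganic acid [M+NH4]+ 394.17, anhydrovinblastine
#' [M+2H]2+ 397.21, serpentine [M+H]+ 349.15). Peonidin-3-O-rutinoside is a
#' flavylium cation and is carried as `[M]+` of the cation composition.
#' Expected retention times are reconstructions on a 7-minute gradient,
#' chosen so that the three C21H24N2O2 isomers are chromatographically
#' resolved; they are not instrument values.
#'
#' @return A `compound_library` data frame with 17 rows.
#' @export
cr_compound_library <- function() {
  df <- data.frame(
    name = c("loganic acid", "secologanin", "strictosidine", "serpentine",
             "ajmalicine", "catharanthine", "tabersonine", "vindolinine",
             "vindoline", "vindorosine", "anhydrovinblastine", "vinblastine",
             "mauritianin", "rutin", "quercetin", "peonidin-3-O-rutinoside",
             "ajmaline"),
    formula = c("C16H24O10", "C17H24O10", "C27H34N2O9", "C21H20N2O3",
                "C21H24N2O3", "C21H24N2O2", "C21H24N2O2", "C21H24N2O2",
                "C25H32N2O6", "C24H30N2O5", "C46H56N4O8", "C46H58N4O9",
                "C33H40O19", "C27H30O16", "C15H10O7", "C28H33O15",
                "C20H26N2O2"),
    adduct = c("[M+NH4]+", "[M+H]+", "[M+H]+", "[M+H]+",
               "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+",
               "[M+H]+", "[M+H]+", "[M+2H]2+", "[M+2H]2+",
               "[M+H]+", "[M+H]+", "[M+H]+", "[M]+",
               "[M+H]+"),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L,
               1L, 1L),
    expected_rt = c(95, 140, 150, 160, 200, 190, 230, 170, 180, 185, 240,
                    250, 130, 125, 210, 120, 165),
    class = c("iridoid", "iridoid", "alkaloid", "alkaloid",
              "alkaloid", "alkaloid", "alkaloid", "alkaloid",
              "alkaloid", "alkaloid", "alkaloid", "alkaloid",
              "flavonoid", "flavonoid", "flavonoid", "anthocyanin",
              "internal_standard"),
    quantifiable = c(rep(TRUE, 16), FALSE),
    is_internal_standard = c(rep(FALSE, 16), TRUE),
    stringsAsFactors = FALSE
  )
  validate_compound_library(df)
}

#' Ion m/z values for every library compound
#'
#' @param library A `compound_library`.
#' @return Named numeric vector of ion m/z, one per compound.
#' @export
library_ion_mz <- function(library = cr_compound_library()) {
  library <- validate_compound_library(library)
  stats::setNames(
    vapply(seq_len(nrow(library)),
           function(i) ion_mz(library$formula[i], library$adduct[i]),
           numeric(1)),
    library$name)
}
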