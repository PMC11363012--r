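# Readers/writers and validation for feature tables, cell metadata, compound
# libraries and calibration series. All files are comma-separated UTF-8 with a
# header row and "." decimals; optional leading "#" comment lines carry the
# generating seed.

#' Construct a feature table
#'
#' The central measurement container: features (id, m/z, retention time) by
#' samples (peak areas).
#'
#' @param features Data frame with columns `feature_id`, `mz` (Th, > 0) and
#'   `rt` (seconds, >= 0); feature ids must be unique.
#' @param areas Numeric matrix, one row per feature and one column per sample,
#'   all entries >= 0. Column names are the sample labels.
#' @param seed Optional integer recorded with the table (and in file headers)
#'   when the table was simulated.
#' @return An object of class `feature_table`: a list with elements
#'   `features`, `samples`, `areas`, `seed`.
#' @export
feature_table <- function(features, areas, seed = NULL) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "rt") %in% names(features)))
  features$feature_id <- as.character(features$feature_id)
  areas <- as.matrix(areas)
  if (nrow(features) != nrow(areas)) {
    stop("area matrix has ", nrow(areas), " rows but ", nrow(features),
         " features")
  }
  dup <- features$feature_id[duplicated(features$feature_id)]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (any(features$mz <= 0)) stop("feature m/z must be > 0")
  if (any(features$rt < 0)) stop("feature rt must be >= 0")
  if (nrow(areas) > 0 && ncol(areas) > 0 && any(areas < 0)) {
    stop("peak areas must be >= 0")
  }
  rownames(areas) <- features$feature_id
  structure(list(features = features[, c("feature_id", "mz", "rt")],
                 samples = colnames(areas), areas = areas,
                 seed = seed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

.write_csv_with_seed <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
}

.read_seed_header <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# seed=")) as.integer(sub("^# seed=", "", first)) else NULL
}

#' Write / read a feature table as CSV
#'
#' Columns: `feature_id`, `mz`, `rt`, then one column per sample. The
#' simulation seed, when present, is written as a leading `# seed=` comment
#' line and restored on read. `read_feature_table(write_feature_table(x))`
#' is the identity on values.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return `read_feature_table` returns a `feature_table`;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$features,
              as.data.frame(table$areas, check.names = FALSE))
  .write_csv_with_seed(df, path, table$seed)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  req <- c("feature_id", "mz", "rt")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("feature table '", path, "' missing column(s): ",
         paste(missing, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), req)
  areas <- as.matrix(df[, sample_cols, drop = FALSE])
  if (length(areas) && any(areas < 0, na.rm = TRUE)) {
    bad <- which(apply(areas < 0, 1, any))[1]
    stop("negative peak area in row ", bad, " (feature '",
         df$feature_id[bad], "') of '", path, "'")
  }
  dup <- which(duplicated(df$feature_id))
  if (length(dup)) {
    stop("duplicate feature id '", df$feature_id[dup[1]], "' in row ",
         dup[1], " of '", path, "'")
  }
  feature_table(df[, req], areas, seed = .read_seed_header(path))
}

#' Construct / validate cell metadata
#'
#' @param df Data frame with columns `cell_id` (unique), `well`, `diameter`
#'   (micrometres, > 0), `fluorescent`, `colored` (logical), `tissue`.
#' @return The validated data frame with class `cell_metadata`.
#' @export
cell_metadata <- function(df) {
  req <- c("cell_id", "well", "diameter", "fluorescent", "colored", "tissue")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("cell metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id(s): ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  }
  if (any(df$diameter <= 0)) {
    stop("nonpositive diameter in row ", which(df$diameter <= 0)[1])
  }
  df$fluorescent <- as.logical(df$fluorescent)
  df$colored <- as.logical(df$colored)
  class(df) <- c("cell_metadata", "data.frame")
  df
}

#' Write / read cell metadata as CSV
#'
#' @param meta A `cell_metadata` data frame.
#' @param path File path.
#' @export
write_cell_metadata <- function(meta, path) {
  .write_csv_with_seed(as.data.frame(meta), path, attr(meta, "seed"))
  invisible(path)
}

#' @rdname write_cell_metadata
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cell_metadata(df)
}

#' Write / read a compound library as CSV
#'
#' @param library A `compound_library`.
#' @param path File path.
#' @export
write_compound_library <- function(library, path) {
  .write_csv_with_seed(as.data.frame(library), path)
  invisible(path)
}

#' @rdname write_compound_library
#' @export
read_compound_library <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_compound_library(df)
}

#' Write / read a calibration series as CSV
#'
#' Long format with columns `compound`, `level` (extract concentration,
#' micromolar), `replicate`, `area`.
#'
#' @param series Calibration series data frame.
#' @param path File path.
#' @export
write_calibration_series <- function(series, path) {
  .write_csv_with_seed(as.data.frame(series), path, attr(series, "seed"))
  invisible(path)
}

#' @rdname write_calibration_series
#' @export
read_calibration_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("compound", "level", "area")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("calibration series '", path, "' missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$level <= 0)) stop("calibration levels must be > 0")
  df
}

#' Pool equal aliquots of every cell extract into a QC sample
#'
#' Taking an equal aliquot from each well and combining them preserves the
#' (intensive) extract concentration, so the pooled per-feature area is the
#' mean of the per-sample areas. The pooled sample is appended to the table
#' under the reserved label `"QC_pool"`.
#'
#' @param table A `feature_table`.
#' @param aliquot Aliquot volume per well in microlitres (default 2).
#' @param extract_volume Extract volume per well in microlitres (default 12);
#'   must exceed `aliquot`.
#' @return The feature table with the pooled sample appended.
#' @export
make_qc_pool <- function(table, aliquot = 2, extract_volume = 12) {
  stopifnot(inherits(table, "feature_table"))
  if (!(aliquot > 0 && aliquot < extract_volume)) {
    stop("aliquot must satisfy 0 < aliquot < extract_volume")
  }
  if (!length(table$samples)) stop("cannot pool an empty table")
  if ("QC_pool" %in% table$samples) stop("table already contains a QC_pool sample")
  pooled <- rowMeans(table$areas)
  areas <- cbind(table$areas, QC_pool = pooled)
  feature_table(table$features, areas, seed = table$seed)
}
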