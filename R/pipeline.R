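# End-to-end orchestration: simulate a tissue preset to files, and run the
# full annotate -> calibrate -> quantify -> partition -> summarize chain from
# files to a machine-readable JSON report. A thin command-line wrapper over
# these functions ships in inst/scripts/scms_pipeline.R.

#' Simulate a tissue preset and write all pipeline inputs
#'
#' Writes five CSV files to `out_dir`: `features.csv` (feature table),
#' `cell_metadata.csv`, `calibration.csv` (external calibration series),
#' `population_truth.csv` (generator ground truth) and `library.csv`
#' (compound library). Identical preset, `n_cells` and seed give
#' byte-identical files.
#'
#' @param preset Preset label (see [preset_labels()]).
#' @param n_cells Optional override of the preset's cell count.
#' @param seed Integer seed driving every random draw.
#' @param out_dir Output directory (created if needed).
#' @param instrument Optional `instrument_config` (default
#'   [instrument_config()]).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_experiment <- function(preset, n_cells = NULL, seed = 1,
                                out_dir = ".", instrument = instrument_config()) {
  config <- build_preset(preset)
  if (!is.null(n_cells)) config$n_cells <- as.integer(n_cells)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(config, seed = seed)
  meas <- simulate_measurement(pop, instrument, seed = seed + 1L)
  calib <- simulate_calibration_series(instrument, seed = seed + 2L)

  truth_df <- cbind(pop$cells,
                    as.data.frame(pop$truth, check.names = FALSE))
  paths <- c(
    features = file.path(out_dir, "features.csv"),
    metadata = file.path(out_dir, "cell_metadata.csv"),
    calibration = file.path(out_dir, "calibration.csv"),
    truth = file.path(out_dir, "population_truth.csv"),
    library = file.path(out_dir, "library.csv"))
  write_feature_table(meas$table, paths[["features"]])
  write_cell_metadata(meas$metadata, paths[["metadata"]])
  write_calibration_series(calib, paths[["calibration"]])
  .write_csv_with_seed(truth_df, paths[["truth"]], seed)
  write_compound_library(instrument$library, paths[["library"]])
  invisible(paths)
}

#' Build a pipeline configuration
#'
#' @param features,metadata,calibration,library Paths to the pipeline input
#'   CSVs (as written by [simulate_experiment()] or produced upstream).
#' @param out_dir Output directory for the report and derived tables.
#' @param tol_ppm Mass tolerance for compound matching (ppm, > 0).
#' @param rt_window Retention-time window for matching (seconds, > 0).
#' @param k,n_restarts,seed k-means parameters; `seed` also drives every
#'   other random choice in the run.
#' @param marker_rules Marker-rule data frame (see
#'   [default_marker_rules()]).
#' @param extract_volume Extract volume in microlitres.
#' @param normalize_is Apply internal-standard normalization.
#' @param thresholds Optional named per-compound thresholds (mM) for summary
#'   fractions.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(features, metadata, calibration, library,
                            out_dir = "scms_out", tol_ppm = 2, rt_window = 10,
                            k = 4, n_restarts = 50, seed = 1,
                            marker_rules = default_marker_rules(),
                            extract_volume = 12, normalize_is = TRUE,
                            thresholds = NULL) {
  if (tol_ppm <= 0 || rt_window <= 0) stop("tolerances must be > 0")
  structure(list(features = features, metadata = metadata,
                 calibration = calibration, library = library,
                 out_dir = out_dir, tol_ppm = tol_ppm, rt_window = rt_window,
                 k = k, n_restarts = n_restarts, seed = as.integer(seed),
                 marker_rules = marker_rules,
                 extract_volume = extract_volume,
                 normalize_is = normalize_is, thresholds = thresholds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()];
#' `marker_rules` may be given as a list of `{marker, threshold, label}`
#' mappings.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$marker_rules)) {
    y$marker_rules <- do.call(rbind, lapply(y$marker_rules, function(r) {
      data.frame(marker = r$marker, threshold = r$threshold, label = r$label,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(y$thresholds)) y$thresholds <- unlist(y$thresholds)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes annotate (feature-to-compound matching) -> calibrate -> quantify
#' -> partition (marker annotation + k-means) -> summarize, and writes
#' `report.json` plus `quant_matrix.csv` and `cell_types.csv` to the
#' configured output directory. The report has a stable key order and
#' records every parameter and seed, so re-running on identical inputs gives
#' identical JSON. Any stage failure raises an error naming the stage.
#'
#' @param config A `pipeline_config` or the path to a YAML config file.
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  table <- .stage("read_features", read_feature_table(config$features))
  meta <- .stage("read_metadata", read_cell_metadata(config$metadata))
  series <- .stage("read_calibration", read_calibration_series(config$calibration))
  library <- .stage("read_library", read_compound_library(config$library))

  assignments <- .stage("annotate",
    match_known_compounds(table, library, config$tol_ppm, config$rt_window))
  curves <- .stage("calibrate",
    fit_calibration_table(series, extract_volume = config$extract_volume))
  quant <- .stage("quantify",
    quantify_cells(table, meta, curves, assignments, library,
                   extract_volume = config$extract_volume,
                   normalize_is = config$normalize_is))
  types <- .stage("partition",
    annotate_cell_types(quant, config$marker_rules))
  mat <- .stage("partition", {
    areas <- t(table$areas)[rownames(quant$concentration),
                            , drop = FALSE]
    log_volume_normalize(areas, quant$volume)
  })
  km <- .stage("partition",
    kmeans_cluster(mat, k = config$k, seed = config$seed,
                   n_restarts = config$n_restarts))
  summary <- .stage("summarize", population_summary(quant, config$thresholds))
  cl_means <- .stage("summarize", cluster_mean_heatmap(mat, km$labels))

  report <- list(
    parameters = list(
      tol_ppm = config$tol_ppm, rt_window = config$rt_window,
      k = config$k, n_restarts = config$n_restarts, seed = config$seed,
      extract_volume = config$extract_volume,
      normalize_is = config$normalize_is),
    inputs = list(n_features = nrow(table$features),
                  n_cells = length(table$samples),
                  n_compounds = sum(library$quantifiable)),
    assignments = assignments,
    calibration = lapply(curves, function(cv) {
      list(compound = cv$compound, slope = cv$slope,
           intercept = cv$intercept, r_squared = cv$r_squared,
           linear_range = cv$linear_range, loq_mol = cv$loq)
    }),
    cell_types = as.list(table(types)),
    population_summary = summary$compounds,
    per_cell = merge(summary$cells,
                     data.frame(cell_id = rownames(quant$concentration),
                                cell_type = unname(types),
                                cluster = km$labels,
                                stringsAsFactors = FALSE),
                     by = "cell_id", sort = TRUE),
    kmeans = list(k = km$k, sizes = km$sizes,
                  tot_withinss = km$tot_withinss),
    cluster_means = as.data.frame(cl_means))

  .stage("report", {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_quant_matrix(quant, file.path(config$out_dir, "quant_matrix.csv"))
    utils::write.csv(data.frame(cell_id = names(types),
                                cell_type = unname(types),
                                cluster = km$labels),
                     file.path(config$out_dir, "cell_types.csv"),
                     row.names = FALSE)
  })
  invisible(report)
}

#' Simulate a preset and quantify it in memory
#'
#' Convenience composition of the full chain — generate population, simulate
#' measurement and calibration series, match features, fit curves, quantify —
#' without touching the filesystem. Sub-seeds for the measurement and
#' calibration stages are derived from `seed`.
#'
#' @param preset Preset label (see [preset_labels()]).
#' @param seed Integer seed.
#' @param instrument An `instrument_config`.
#' @param n_cells Optional cell-count override.
#' @return List with `population` (a `cell_population`), `quant` (a
#'   `quant_matrix`), `assignments`, `curves` and `table`.
#' @export
quantify_preset <- function(preset, seed = 1, instrument = instrument_config(),
                            n_cells = NULL) {
  config <- build_preset(preset)
  if (!is.null(n_cells)) config$n_cells <- as.integer(n_cells)
  pop <- generate_population(config, seed = seed)
  meas <- simulate_measurement(pop, instrument, seed = seed + 1L)
  calib <- simulate_calibration_series(instrument, seed = seed + 2L)
  assignments <- match_known_compounds(meas$table, instrument$library)
  curves <- fit_calibration_table(calib,
                                  extract_volume = instrument$extract_volume)
  quant <- quantify_cells(meas$table, meas$metadata, curves, assignments,
                          instrument$library,
                          extract_volume = instrument$extract_volume)
  list(population = pop, quant = quant, assignments = assignments,
       curves = curves, table = meas$table)
}
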