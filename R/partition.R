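# Population partitioning: volume-normalized log transform, hierarchical and
# k-means clustering, marker-based cell-type annotation, and per-population
# summaries.

#' Log-transform and volume-normalize a cell x feature matrix
#'
#' `value = log10(area / volume + pseudocount)`: peak areas are first
#' normalized by the calculated cell volume (so larger cells are not scored
#' as more concentrated) and then log-transformed.
#'
#' @param areas Numeric matrix, cells in rows, features/compounds in columns,
#'   entries >= 0.
#' @param volumes Cell volumes in pL, one per row, all > 0.
#' @param pseudocount Added inside the log (default 1 on the
#'   volume-normalized area scale).
#' @return Transformed matrix of the same shape.
#' @export
log_volume_normalize <- function(areas, volumes, pseudocount = 1) {
  areas <- as.matrix(areas)
  if (length(volumes) != nrow(areas)) {
    stop("need one volume per row of the area matrix")
  }
  if (any(volumes <= 0)) stop("volumes must be > 0")
  if (any(areas < 0)) stop("areas must be >= 0")
  log10(sweep(areas, 1, volumes, "/") + pseudocount)
}

# leaf set of each internal node of an hclust merge tree
.merge_leafsets <- function(merge) {
  n <- nrow(merge) + 1L
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    get <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- c(get(merge[i, 1]), get(merge[i, 2]))
  }
  sets
}

#' Hierarchical clustering of cells
#'
#' Agglomerative clustering with deterministic leaf ordering: at every
#' internal node the subtree with more leaves is placed first (ties keep the
#' merge order), so identical inputs always give identical dendrograms and
#' leaf sequences.
#'
#' @param matrix Numeric matrix, cells in rows (>= 2 rows, no missing
#'   values).
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return List with `hclust` (the tree), `order` (deterministic leaf order,
#'   row indices) and `labels`.
#' @export
hierarchical_cluster <- function(matrix, distance = "euclidean",
                                 linkage = "ward.D2") {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stop("hierarchical clustering needs at least 2 cells")
  if (anyNA(matrix)) stop("matrix must not contain missing values")
  hc <- stats::hclust(stats::dist(matrix, method = distance), method = linkage)
  sets <- .merge_leafsets(hc$merge)
  ord <- local({
    walk <- function(j) {
      if (j < 0) return(-j)
      a <- hc$merge[j, 1]; b <- hc$merge[j, 2]
      size <- function(k) if (k < 0) 1L else length(sets[[k]])
      if (size(b) > size(a)) { tmp <- a; a <- b; b <- tmp }
      c(walk(a), walk(b))
    }
    walk(nrow(hc$merge))
  })
  list(hclust = hc, order = ord,
       labels = if (is.null(rownames(matrix))) as.character(seq_len(nrow(matrix)))
                else rownames(matrix))
}

#' Does a dendrogram contain a clade with exactly these leaves?
#'
#' Utility for testing co-clustering claims: TRUE when some internal node's
#' leaf set equals `leaves` (row indices), or when `leaves` is a single leaf.
#'
#' @param hc An `hclust` object.
#' @param leaves Integer vector of leaf indices.
#' @return Logical scalar.
#' @export
tree_contains_clade <- function(hc, leaves) {
  leaves <- sort(unique(as.integer(leaves)))
  if (length(leaves) <= 1) return(TRUE)
  sets <- .merge_leafsets(hc$merge)
  any(vapply(sets, function(s) identical(sort(s), leaves), logical(1)))
}

#' k-means clustering of cells
#'
#' Runs [stats::kmeans()] with `n_restarts` seeded random starts and keeps
#' the solution with the lowest total within-cluster dispersion. Features are
#' standardized per column by default, since compound classes span very
#' different intensity scales.
#'
#' @param matrix Numeric matrix, cells in rows.
#' @param k Number of clusters (default 4), `1 <= k <=` number of cells.
#' @param seed Integer seed; identical matrix and seed give identical labels.
#' @param n_restarts Random restarts (default 50).
#' @param standardize Scale each column to unit variance first (default
#'   TRUE; constant columns are left unscaled).
#' @return An object of class `cluster_result`: list with `labels` (integer
#'   vector in `1..k`), `k`, `seed`, `tot_withinss`, `sizes`, `centers`.
#' @export
kmeans_cluster <- function(matrix, k = 4, seed = 1, n_restarts = 50,
                           standardize = TRUE) {
  x <- as.matrix(matrix)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of cells (", nrow(x), ")")
  if (anyNA(x)) stop("matrix must not contain missing values")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  structure(list(labels = unname(km$cluster), k = as.integer(k),
                 seed = as.integer(seed), tot_withinss = km$tot.withinss,
                 sizes = as.integer(km$size), centers = km$centers),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k=", x$k, ", sizes ", paste(x$sizes, collapse = "/"),
      ", within-SS ", format(x$tot_withinss, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Default marker rules for leaf cell-type annotation
#'
#' Serpentine (the fluorescent idioblast marker) takes priority over loganic
#' acid (the IPAP marker); cells matching neither rule fall back to
#' `"other"`. Thresholds are 1 mM, comfortably above the LOQ-equivalent
#' concentration of either compound in any cell of the studied size range.
#'
#' @return Data frame `marker`, `threshold` (mM), `label`, in priority order.
#' @export
default_marker_rules <- function() {
  data.frame(marker = c("serpentine", "loganic acid"),
             threshold = c(1, 1),
             label = c("idioblast", "IPAP"),
             stringsAsFactors = FALSE)
}

#' Annotate cell types from marker metabolites
#'
#' Rules are applied in priority order: the first rule whose marker compound
#' is quantified above its threshold in a cell assigns that cell's label;
#' cells matching no rule receive the fallback label. Entries flagged
#' `below_loq` or `absent` never trigger a rule.
#'
#' @param quant A `quant_matrix`.
#' @param rules Data frame `marker`, `threshold` (mM, > 0), `label` in
#'   priority order; labels must be unique.
#' @param fallback Label for unmatched cells (default `"other"`).
#' @return Character vector of labels, one per cell, named by cell id.
#' @export
annotate_cell_types <- function(quant, rules = default_marker_rules(),
                                fallback = "other") {
  stopifnot(inherits(quant, "quant_matrix"),
            all(c("marker", "threshold", "label") %in% names(rules)))
  if (any(rules$threshold <= 0)) stop("marker thresholds must be > 0")
  if (anyDuplicated(rules$label)) stop("marker rule labels must be unique")
  missing <- setdiff(rules$marker, colnames(quant$concentration))
  if (length(missing)) {
    stop("unknown marker compound(s): ", paste(missing, collapse = ", "))
  }
  labels <- rep(fallback, nrow(quant$concentration))
  assigned <- logical(length(labels))
  for (i in seq_len(nrow(rules))) {
    v <- quant$concentration[, rules$marker[i]]
    hit <- !assigned & !is.na(v) &
      quant$status[, rules$marker[i]] == "quantified" & v >= rules$threshold[i]
    labels[hit] <- rules$label[i]
    assigned <- assigned | hit
  }
  stats::setNames(labels, rownames(quant$concentration))
}

#' Per-compound and per-cell population summaries
#'
#' Below-LOQ and absent entries are censored: they count as zero in
#' fractions and are excluded from medians and maxima.
#'
#' @param quant A `quant_matrix`.
#' @param thresholds Optional named numeric vector of per-compound
#'   concentration thresholds (mM) for the `frac_above_threshold` column.
#' @return List with `compounds` (data frame: `compound`, `n_cells`,
#'   `n_quantified`, `frac_quantified`, `frac_above_threshold` (NA when no
#'   threshold given), `max_mM` (NA when nothing quantified), `median_mM`)
#'   and `cells` (data frame: `cell_id`, `total_alkaloid_mM`, the sum of
#'   quantified alkaloid-class concentrations).
#' @export
population_summary <- function(quant, thresholds = NULL) {
  stopifnot(inherits(quant, "quant_matrix"))
  conc <- quant$concentration
  status <- quant$status
  if (!nrow(conc)) stop("empty quant matrix")
  cmp <- colnames(conc)
  per_cmp <- do.call(rbind, lapply(cmp, function(c0) {
    v <- conc[, c0]
    q <- status[, c0] == "quantified" & !is.na(v)
    thr <- if (!is.null(thresholds) && c0 %in% names(thresholds))
      thresholds[[c0]] else NA_real_
    data.frame(
      compound = c0, n_cells = nrow(conc), n_quantified = sum(q),
      frac_quantified = mean(q),
      frac_above_threshold = if (is.na(thr)) NA_real_ else mean(q & v >= thr),
      max_mM = if (any(q)) max(v[q]) else NA_real_,
      median_mM = if (any(q)) stats::median(v[q]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  alk <- cmp[cmp %in% quant$library$name[quant$library$class == "alkaloid"]]
  total_alk <- if (length(alk)) {
    a <- conc[, alk, drop = FALSE]
    a[status[, alk, drop = FALSE] != "quantified" | is.na(a)] <- 0
    rowSums(a)
  } else rep(0, nrow(conc))
  list(compounds = per_cmp,
       cells = data.frame(cell_id = rownames(conc),
                          total_alkaloid_mM = unname(total_alk),
                          stringsAsFactors = FALSE))
}

#' Cluster-mean intensity table
#'
#' Per-cluster column means of a (typically log-volume-normalized) matrix:
#' the numeric content of a cluster x compound heat map.
#'
#' @param matrix Numeric matrix, cells in rows.
#' @param labels Cluster labels, one per row.
#' @return Matrix, one row per cluster (sorted by cluster id), one column per
#'   compound.
#' @export
cluster_mean_heatmap <- function(matrix, labels) {
  matrix <- as.matrix(matrix)
  if (length(labels) != nrow(matrix)) {
    stop("need one cluster label per row (", nrow(matrix), " rows, ",
         length(labels), " labels)")
  }
  ids <- sort(unique(labels))
  out <- t(vapply(ids, function(l) colMeans(matrix[labels == l, , drop = FALSE]),
                  numeric(ncol(matrix))))
  rownames(out) <- as.character(ids)
  colnames(out) <- colnames(matrix)
  out
}
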