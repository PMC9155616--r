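#' Silhouette widths and median silhouette index
#'
#' Classical silhouette: for each observation, `s = (b - a) / max(a, b)`
#' with `a` the mean Euclidean distance to its own cluster and `b` the
#' smallest mean distance to another cluster. Singleton clusters and
#' degenerate observations (all distances zero) receive `s = 0` by
#' convention. The median over observations (MSI) summarises cluster
#' cohesion of a projection.
#'
#' @param points observations x dims numeric matrix (typically PC scores).
#' @param labels per-observation cluster labels; at least two non-empty
#'   clusters.
#' @return List with `widths` (per observation) and `msi` (their median).
#' @export
silhouette_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) {
    stop("labels length must equal the number of observations")
  }
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least two clusters")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist = stats::dist(points))
  widths <- sil[, "sil_width"]
  widths[!is.finite(widths)] <- 0
  list(widths = unname(widths), msi = stats::median(widths))
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same observations, corrected
#' for chance via the contingency-table expected index; 1 for identical
#' partitions (up to renaming), about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A single number, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Between- over within-cluster distance ratio
#'
#' Mean pairwise Euclidean distance between observations of different
#' clusters divided by the mean pairwise distance within clusters. Values
#' near 1 indicate no separation; the ratio grows as clusters move apart.
#'
#' @inheritParams silhouette_index
#' @return A positive number.
#' @export
distance_ratio <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) {
    stop("labels length must equal the number of observations")
  }
  if (length(unique(labels)) < 2L) {
    stop("distance ratio requires at least two clusters")
  }
  d <- as.matrix(stats::dist(points))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (length(within) == 0L) {
    stop("no within-cluster pairs (all clusters are singletons)")
  }
  mean(between) / mean(within)
}

#' Clustering-quality report for a projection
#'
#' Computes the three projection-quality metrics on a set of points (PC
#' scores): median silhouette index against the true labels, distance
#' ratio, and - when a second labelling such as a de novo clustering is
#' supplied - the adjusted Rand index between the two labelings.
#'
#' @param points observations x dims matrix of projected coordinates.
#' @param labels_true reference labels.
#' @param labels_pred optional second labelling for the ARI (defaults to
#'   `labels_true`, giving ARI 1).
#' @return A list of class `cluster_metric_report`: `msi`, `ari`,
#'   `distance_ratio`, `per_obs_silhouette`.
#' @export
evaluate_projection <- function(points, labels_true, labels_pred = NULL) {
  sil <- silhouette_index(points, labels_true)
  if (is.null(labels_pred)) labels_pred <- labels_true
  structure(
    list(msi = sil$msi,
         ari = ari(labels_true, labels_pred),
         distance_ratio = distance_ratio(points, labels_true),
         per_obs_silhouette = sil$widths),
    class = "cluster_metric_report")
}

#' @export
print.cluster_metric_report <- function(x, ...) {
  cat(sprintf("<cluster_metric_report> MSI %.3f | ARI %.3f | distance ratio %.2f\n",
              x$msi, x$ari, x$distance_ratio))
  invisible(x)
}
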