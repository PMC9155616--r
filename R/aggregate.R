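#' Bootstrap pseudo-bulk aggregation of clustered cells
#'
#' Turns a clustered single-cell matrix into pseudo-bulk samples that mimic
#' the structure and variation of bulk replicates. For each cluster with
#' `N_t` cells, `N_t` cells are drawn with replacement and averaged gene by
#' gene to give one pseudo-bulk sample; this bootstrap is repeated `B_t`
#' times (default `B_t = N_t`). Pseudo-bulk labels are inherited from the
#' source cluster. Averaging requires additive units (raw counts, CPM or
#' TPM): log-scale values are refused because their average is not a valid
#' bulk profile.
#'
#' Each cluster is resampled from its own seed substream (derived from the
#' global seed and the cluster name), so adding or removing a cluster does
#' not perturb the samples generated for the others.
#'
#' @param query single-cell matrix, genes x cells, additive units.
#' @param clusters per-cell cluster labels (length `ncol(query)`).
#' @param n_boot `NULL` for `B_t = N_t`, a single integer used for every
#'   cluster, or a named vector/list mapping cluster to `B_t` (each >= 1).
#' @param seed integer seed driving all resampling.
#' @param min_cells clusters smaller than this are skipped with a warning
#'   (default 10).
#' @return A list: `pseudobulk` (`expr_mat`, genes x pseudo-bulk samples)
#'   and `labels` (source cluster of each pseudo-bulk sample).
#' @export
aggregate_cells <- function(query, clusters, n_boot = NULL, seed = 1L,
                            min_cells = 10L) {
  query <- as_expr(query)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(query)) {
    stop("clusters length must equal the number of cells")
  }
  unit <- expr_unit(query)
  if (unit == "rank") {
    stop("pseudo-bulk aggregation requires additive units; ",
         "rank-transformed values cannot be averaged meaningfully")
  }
  if (unit == "unknown") {
    v <- unclass(query)
    if (any(v != round(v)) && max(v) < 50) {
      stop("query values look log-transformed (non-integer, max < 50); ",
           "aggregation requires additive units (counts, CPM or TPM). ",
           "Undo the log transformation first.")
    }
  }

  cl_names <- unique(clusters)
  sizes <- table(factor(clusters, levels = cl_names))
  keep <- cl_names[sizes[cl_names] >= min_cells]
  if (length(keep) < length(cl_names)) {
    warning("skipping cluster(s) below min_cells = ", min_cells, ": ",
            paste(setdiff(cl_names, keep), collapse = ", "))
  }
  if (length(keep) == 0L) {
    stop("no cluster has at least min_cells = ", min_cells, " cells")
  }

  boot_for <- function(cl, n_t) {
    if (is.null(n_boot)) return(n_t)
    if (length(n_boot) == 1L && is.null(names(n_boot))) {
      return(as.integer(n_boot))
    }
    b <- n_boot[[cl]]
    if (is.null(b) || is.na(b)) n_t else as.integer(b)
  }

  out <- vector("list", length(keep))
  labs <- character(0)
  for (ci in seq_along(keep)) {
    cl <- keep[ci]
    idx <- which(clusters == cl)
    n_t <- length(idx)
    b_t <- boot_for(cl, n_t)
    if (b_t < 1L) stop("B_t must be >= 1 for cluster ", cl)
    block <- with_seed(seed + str_seed(cl), {
      vapply(seq_len(b_t), function(b) {
        rowMeans(unclass(query)[, idx[sample.int(n_t, n_t, replace = TRUE)],
                                drop = FALSE])
      }, numeric(nrow(query)))
    })
    colnames(block) <- paste0(cl, "_pb", seq_len(b_t))
    out[[ci]] <- block
    labs <- c(labs, rep(cl, b_t))
  }
  pb <- do.call(cbind, out)
  rownames(pb) <- rownames(query)
  list(pseudobulk = expr_matrix(pb, unit = if (unit == "unknown") "unknown"
                                           else unit),
       labels = stats::setNames(labs, colnames(pb)))
}

#' Sparsity of pseudo-bulk clusters
#'
#' Fraction of zero entries in each cluster's pseudo-bulk block. Clusters
#' whose sparsity is strictly above `threshold` are flagged: residual
#' sparsity after aggregation indicates the cluster is too small or too
#' heterogeneous for its pseudo-bulk samples to project reliably onto a
#' bulk atlas.
#'
#' @param pseudobulk genes x pseudo-bulk matrix, as from
#'   [aggregate_cells()].
#' @param labels per-sample cluster labels.
#' @param threshold flag clusters with sparsity strictly greater than this
#'   (default 0.15).
#' @return A data.frame with one row per cluster: `cluster`, `sparsity`,
#'   `flagged`.
#' @export
cluster_sparsity <- function(pseudobulk, labels, threshold = 0.15) {
  pseudobulk <- as_expr(pseudobulk)
  labels <- as.character(labels)
  if (length(labels) != ncol(pseudobulk)) {
    stop("labels length must equal the number of pseudo-bulk samples")
  }
  cl <- unique(labels)
  sp <- vapply(cl, function(c) {
    mean(unclass(pseudobulk)[, labels == c, drop = FALSE] == 0)
  }, numeric(1))
  data.frame(cluster = cl, sparsity = unname(sp),
             flagged = unname(sp > threshold), row.names = NULL)
}
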