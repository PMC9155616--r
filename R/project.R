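#' Project query observations onto an atlas
#'
#' Maps query cells into the reference PC space: both sides are subset to
#' their overlapping genes (atlas gene order), the query columns are
#' rank-transformed on the reduced gene set, centred with the reference's
#' per-gene centring means (not the query's own, so both datasets share one
#' coordinate origin), and multiplied by the atlas gene loadings. Because
#' ranks are invariant to monotone per-cell transformations, the projection
#' needs no batch correction between platforms.
#'
#' @param atlas an `atlas_model` from [fit_atlas()].
#' @param query genes x cells matrix (any additive or rank unit; ranks are
#'   recomputed on the overlap).
#' @param min_overlap minimum number of overlapping genes required
#'   (default 50).
#' @return An object of class `projection_result` with `query_scores`
#'   (cells x n_pc), `ref_scores` (copied from the atlas), `ref_labels`,
#'   `overlap_genes` and `overlap_fraction` (relative to the atlas gene
#'   set).
#' @export
project_query <- function(atlas, query, min_overlap = 50L) {
  stopifnot(inherits(atlas, "atlas_model"))
  query <- as_expr(query)
  genes <- atlas$genes[atlas$genes %in% rownames(query)]
  if (length(genes) == 0L) {
    stop("no overlap between atlas genes and query genes")
  }
  if (length(genes) < min_overlap) {
    stop("gene overlap (", length(genes), ") below the required minimum (",
         min_overlap, ")")
  }
  frac <- length(genes) / length(atlas$genes)
  message(sprintf("projecting on %d/%d atlas genes (%.1f%% overlap)",
                  length(genes), length(atlas$genes), 100 * frac))
  qr <- rank_transform(unclass(query)[genes, , drop = FALSE])
  centred <- unclass(qr) - atlas$centering_means[genes]
  scores <- t(centred) %*% atlas$loadings[genes, , drop = FALSE]
  structure(
    list(query_scores = scores,
         ref_scores = atlas$scores,
         ref_labels = atlas$sample_labels,
         overlap_genes = genes,
         overlap_fraction = frac,
         query_ranked = qr),
    class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d query cells on %d reference samples, %d PCs (%.1f%% gene overlap)\n",
              nrow(x$query_scores), nrow(x$ref_scores), ncol(x$query_scores),
              100 * x$overlap_fraction))
  invisible(x)
}

#' Joint diffusion-map embedding of reference and query
#'
#' Refines the visual landscape by running a diffusion map on the
#' concatenated reference and query PC scores. The Gaussian kernel uses a
#' single global bandwidth equal to two times the maximum pairwise distance
#' among the reference samples - large enough that the joint landscape
#' cannot fall apart into disconnected pieces dominated by reference
#' structure. The constant eigenvector (eigenvalue 1) is omitted; the top
#' three non-trivial eigenvectors, scaled by \eqn{\lambda^t}, give the
#' diffusion coordinates.
#'
#' @param projection a `projection_result` from [project_query()].
#' @param n_pc_dm number of PC columns used; `NULL` (default) takes the
#'   elbow of the atlas eigenvalue scree (largest second difference), with
#'   a minimum of 3.
#' @param t_dm diffusion time applied to the eigenvalue scaling
#'   (default 1).
#' @param atlas_eigenvalues eigenvalue scree used for the elbow when
#'   `n_pc_dm` is `NULL`; defaults to reading the score variances from the
#'   projection.
#' @param use_left use left eigenvectors of the Markov operator
#'   (default TRUE); set FALSE for the right-eigenvector convention.
#' @return List with `coords` ((samples+cells) x 3 diffusion coordinates,
#'   reference rows first), `eigvals` (the three retained eigenvalues),
#'   `bandwidth` and `source` (`"reference"`/`"query"` per row).
#' @export
dm_embed <- function(projection, n_pc_dm = NULL, t_dm = 1,
                     atlas_eigenvalues = NULL, use_left = TRUE) {
  stopifnot(inherits(projection, "projection_result"))
  ref <- projection$ref_scores
  qry <- projection$query_scores
  if (nrow(ref) + nrow(qry) < 4L) {
    stop("diffusion map needs at least 4 observations")
  }
  if (is.null(n_pc_dm)) {
    eig <- if (is.null(atlas_eigenvalues)) {
      apply(ref, 2L, stats::var)
    } else {
      atlas_eigenvalues
    }
    n_pc_dm <- if (length(eig) <= 3L) length(eig) else {
      d2 <- diff(diff(eig))
      max(3L, which.max(abs(d2)) + 1L)
    }
  }
  n_pc_dm <- min(n_pc_dm, ncol(ref))
  s <- rbind(ref[, seq_len(n_pc_dm), drop = FALSE],
             qry[, seq_len(n_pc_dm), drop = FALSE])
  bandwidth <- 2 * max(stats::dist(ref[, seq_len(n_pc_dm), drop = FALSE]))
  if (bandwidth <= 0) stop("degenerate reference: all samples coincide")
  d <- as.matrix(stats::dist(s))
  k <- exp(-(d / bandwidth)^2)
  deg <- rowSums(k)
  sq <- sqrt(deg)
  m <- k / outer(sq, sq)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vecs <- if (use_left) e$vectors * sq else e$vectors / sq
  # eigenvalue 1 / constant eigenvector is trivial; keep the next three
  keep <- 2:4
  lam <- e$values[keep]
  coords <- sweep(vecs[, keep, drop = FALSE], 2L, lam^t_dm, "*")
  rownames(coords) <- c(rownames(ref), rownames(qry))
  colnames(coords) <- paste0("DC", 1:3)
  list(coords = coords, eigvals = lam, bandwidth = bandwidth,
       source = c(rep("reference", nrow(ref)), rep("query", nrow(qry))))
}
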