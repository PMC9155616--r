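#' Within-observation rank transformation
#'
#' Replaces every observation (column) by the fractional ranks of its values:
#' average-tie ranks divided by the number of genes, so transformed profiles
#' lie in (0, 1]. Rank transformation makes profiles from different platforms
#' and library sizes directly comparable, because it is invariant to any
#' strictly increasing per-observation transformation of the raw values.
#' All zeros in a column form a single tie group sharing the lowest average
#' rank.
#'
#' @param mat genes x observations matrix (or [expr_matrix()]) of
#'   non-negative values.
#' @return An `expr_mat` with unit `"rank"`, same dimnames, values in (0, 1].
#' @examples
#' rank_transform(matrix(c(0, 0, 5, 10), 4, 1))
#' @export
rank_transform <- function(mat) {
  mat <- as_expr(mat)
  g <- nrow(mat)
  r <- apply(unclass(mat), 2L, function(col) rank(col, ties.method = "average"))
  r <- matrix(r, nrow = g, dimnames = dimnames(mat))
  expr_matrix(r / g, unit = "rank")
}

#' Hellinger-distance discriminant score per gene
#'
#' Scores how well each gene's rank distribution separates one class of
#' observations from the rest. For each gene and each class, ranks inside
#' and outside the class are binned into `n_bins` equal-width bins on
#' \[0, 1\] and compared by the Hellinger distance
#' \eqn{H = \sqrt{1 - \sum_b \sqrt{p_b q_b}}} (one minus the Bhattacharyya
#' coefficient, square-rooted). The gene score is the maximum over classes,
#' so it lies in \[0, 1\]: 0 when the in/out distributions coincide in every
#' class, 1 when some class occupies bins disjoint from the rest.
#'
#' @param ranked rank-transformed matrix (unit `"rank"`), genes x
#'   observations.
#' @param labels per-observation class labels (length `ncol(ranked)`); at
#'   least two classes, each non-empty.
#' @param n_bins number of equal-width bins on \[0, 1\] (default 10).
#' @return Named numeric vector of per-gene scores in \[0, 1\].
#' @export
hd_score <- function(ranked, labels, n_bins = 10L) {
  ranked <- as_expr(ranked)
  if (expr_unit(ranked) != "rank") {
    stop("hd_score expects a rank-transformed matrix (unit = 'rank')")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(ranked)) {
    stop("labels length must equal the number of observations")
  }
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("hd_score needs at least two classes")
  }
  # bin index per entry; ranks are in (0, 1] so ceiling lands in 1..n_bins
  bins <- ceiling(unclass(ranked) * n_bins)
  bins[bins > n_bins] <- n_bins
  bins[bins < 1L] <- 1L
  scores <- rep(0, nrow(ranked))
  for (cl in classes) {
    inside <- labels == cl
    n_in <- sum(inside)
    n_out <- sum(!inside)
    if (n_in == 0L || n_out == 0L) {
      stop("every class must have at least one observation inside and outside")
    }
    bc <- rep(0, nrow(ranked)) # Bhattacharyya coefficient per gene
    for (b in seq_len(n_bins)) {
      p <- rowSums(bins[, inside, drop = FALSE] == b) / n_in
      q <- rowSums(bins[, !inside, drop = FALSE] == b) / n_out
      bc <- bc + sqrt(p * q)
    }
    h <- sqrt(pmax(0, 1 - pmin(1, bc)))
    scores <- pmax(scores, h)
  }
  names(scores) <- rownames(ranked)
  scores
}

#' Select top discriminant genes
#'
#' Keeps the `n_genes` genes with the highest Hellinger-distance scores.
#' Ties at the cutoff are broken by gene identifier order, so selection is
#' stable and reproducible.
#'
#' @param ranked rank-transformed reference matrix (used for gene ids).
#' @param hd named per-gene score vector, as from [hd_score()].
#' @param n_genes number of genes to keep (positive, at most the gene count).
#' @return Character vector of selected gene identifiers, ordered by
#'   decreasing score then identifier.
#' @export
select_genes <- function(ranked, hd, n_genes) {
  ranked <- as_expr(ranked)
  if (n_genes <= 0) {
    stop("n_genes must be positive")
  }
  if (n_genes > nrow(ranked)) {
    stop("n_genes exceeds the number of genes (", nrow(ranked), ")")
  }
  ids <- rownames(ranked)
  hd <- hd[ids]
  ord <- order(-hd, ids, method = "radix")
  ids[ord][seq_len(n_genes)]
}

# Elbow of a descending eigenvalue scree: the component just before the
# largest drop in consecutive differences.
elbow_point <- function(eigenvalues, min_keep = 2L) {
  if (length(eigenvalues) <= min_keep) {
    return(length(eigenvalues))
  }
  drops <- -diff(eigenvalues)
  max(min_keep, which.max(drops))
}

#' Build a bulk reference atlas
#'
#' Full reference pipeline: rank-transform the bulk matrix, score genes by
#' Hellinger distance against the sample labels, keep the top `n_genes`
#' discriminant genes, rank-transform again on the reduced gene set (ranks
#' must be re-allocated once genes are dropped), centre each gene by its
#' mean, and decompose by PCA. Gene centring implies the PC scores are
#' column-centred; eigenvalues are the per-component variances (denominator
#' `n_samples - 1`) and sum to the total centred variance.
#'
#' Genes with zero variance after re-ranking carry no information for the
#' PCA and are dropped with a warning.
#'
#' @param ref bulk reference matrix, genes x samples (non-negative).
#' @param labels per-sample class labels.
#' @param n_genes number of discriminant genes to retain (default 2000,
#'   capped at the gene count).
#' @param n_pc number of principal components to keep; `NULL` (default)
#'   keeps components up to the elbow of the eigenvalue scree (largest drop
#'   in consecutive eigenvalues).
#' @param n_bins bins for the Hellinger score (see [hd_score()]).
#' @return An object of class `atlas_model` with elements `genes`,
#'   `hd_scores`, `centering_means`, `loadings` (genes x n_pc, orthonormal,
#'   each column oriented so its largest-magnitude entry is positive),
#'   `scores` (samples x n_pc), `eigenvalues`, `sample_labels` and `ranked`
#'   (the re-ranked reference on the retained genes, used downstream for
#'   identity predictors).
#' @export
fit_atlas <- function(ref, labels, n_genes = 2000L, n_pc = NULL,
                      n_bins = 10L) {
  ref <- as_expr(ref)
  labels <- as.character(labels)
  if (length(labels) != ncol(ref)) {
    stop("labels length must equal the number of reference samples")
  }
  n_genes <- min(n_genes, nrow(ref))

  ranked <- rank_transform(ref)
  hd <- hd_score(ranked, labels, n_bins = n_bins)
  genes <- select_genes(ranked, hd, n_genes)

  # re-rank on the reduced gene set: rank allocation changes with the genes
  rr <- rank_transform(unclass(ref)[genes, , drop = FALSE])
  vars <- apply(unclass(rr), 1L, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " gene(s) with zero variance after re-ranking ",
            "were dropped before PCA")
    genes <- genes[vars > 0]
    rr <- rank_transform(unclass(ref)[genes, , drop = FALSE])
  }

  mu <- rowMeans(rr)
  centred <- unclass(rr) - mu
  n <- ncol(centred)
  sv <- svd(centred)
  eig_all <- sv$d^2 / (n - 1)
  attainable <- sum(sv$d > max(sv$d) * 1e-10)

  if (is.null(n_pc)) {
    n_pc <- min(elbow_point(eig_all[seq_len(attainable)]), attainable)
  }
  if (n_pc > attainable) {
    stop("n_pc = ", n_pc, " exceeds the rank of the centred matrix; ",
         "attainable maximum is ", attainable)
  }

  loadings <- sv$u[, seq_len(n_pc), drop = FALSE]
  scores <- sv$v[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)

  # orient each component so its largest-magnitude loading is positive
  for (k in seq_len(n_pc)) {
    peak <- which.max(abs(loadings[, k]))
    if (loadings[peak, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(n_pc)))
  dimnames(scores) <- list(colnames(ref), paste0("PC", seq_len(n_pc)))

  structure(
    list(genes = genes,
         hd_scores = hd[genes],
         centering_means = stats::setNames(mu, genes),
         loadings = loadings,
         scores = scores,
         eigenvalues = eig_all[seq_len(n_pc)],
         sample_labels = stats::setNames(labels, colnames(ref)),
         ranked = rr),
    class = "atlas_model")
}

#' @export
print.atlas_model <- function(x, ...) {
  cat(sprintf(paste0("<atlas_model> %d genes, %d samples, %d PCs ",
                     "(%.1f%% variance), %d classes\n"),
              length(x$genes), nrow(x$scores), ncol(x$scores),
              100 * sum(x$eigenvalues) /
                max(sum(apply(unclass(x$ranked), 1, stats::var)),
                    .Machine$double.eps),
              length(unique(x$sample_labels))))
  invisible(x)
}
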