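#' Reference cell-type predictors for identity scoring
#'
#' Builds the predictor profiles that query cells are regressed on. In
#' `"type_mean"` mode each cell type contributes the gene-wise mean of its
#' re-ranked reference profiles. In `"subcluster_medoid"` mode each type is
#' partitioned into up to `n_sub` sub-clusters by k-medoids on the atlas PC
#' scores and every medoid sample's profile is stored; at scoring time each
#' query cell is regressed on its nearest medoid per type, which respects
#' within-type biological heterogeneity in comprehensive atlases.
#'
#' @param atlas an `atlas_model`.
#' @param mode `"type_mean"` or `"subcluster_medoid"`.
#' @param n_sub maximum sub-clusters per type (default 3, capped at the
#'   type's sample count).
#' @return An object of class `identity_predictors`: `mode`, `types`, and
#'   per type either a single mean profile or a list of medoid profiles
#'   with their sample ids and PC scores.
#' @export
build_predictors <- function(atlas, mode = c("subcluster_medoid", "type_mean"),
                             n_sub = 3L) {
  stopifnot(inherits(atlas, "atlas_model"))
  mode <- match.arg(mode)
  labels <- atlas$sample_labels
  types <- unique(labels)
  if (length(types) < 2L) {
    stop("the atlas must contain at least two labelled types")
  }
  rr <- unclass(atlas$ranked)
  out <- vector("list", length(types))
  names(out) <- types
  for (ty in types) {
    idx <- which(labels == ty)
    if (mode == "type_mean") {
      out[[ty]] <- list(profile = rowMeans(rr[, idx, drop = FALSE]))
    } else {
      k <- min(n_sub, length(idx))
      if (k == 1L || length(idx) <= 2L) {
        med_idx <- idx[[1L]]
        if (length(idx) > 1L) {
          # medoid of a tiny set: member minimizing total distance
          d <- as.matrix(stats::dist(atlas$scores[idx, , drop = FALSE]))
          med_idx <- idx[which.min(rowSums(d))]
        }
        med_idx <- med_idx[1L]
        out[[ty]] <- list(medoid_ids = names(labels)[med_idx],
                          profiles = rr[, med_idx, drop = FALSE],
                          pc = atlas$scores[med_idx, , drop = FALSE])
      } else {
        pam <- cluster::pam(atlas$scores[idx, , drop = FALSE], k = k,
                            pamonce = 5)
        med <- idx[pam$id.med]
        out[[ty]] <- list(medoid_ids = names(labels)[med],
                          profiles = rr[, med, drop = FALSE],
                          pc = atlas$scores[med, , drop = FALSE])
      }
    }
  }
  structure(list(mode = mode, types = types, predictors = out,
                 genes = atlas$genes),
            class = "identity_predictors")
}

# Solve min ||sqrt(H)(x - R b)||^2 s.t. b >= 0, sum(b) <= 1 via quadprog.
# A tiny ridge keeps the Hessian positive definite and resolves degenerate
# optima toward the minimum-norm solution.
rls_solve <- function(R, x, w, ridge = 1e-10) {
  k <- ncol(R)
  hw <- R * w
  D <- crossprod(hw, R)
  D <- (D + t(D)) / 2 + diag(ridge, k)
  d <- drop(crossprod(hw, x))
  A <- cbind(rep(-1, k), diag(k)) # -sum(b) >= -1 ; b >= 0
  b0 <- c(-1, rep(0, k))
  sol <- quadprog::solve.QP(D, d, A, b0)
  beta <- sol$solution
  beta[beta < 0 & beta > -1e-10] <- 0
  beta
}

#' Continuum cell-identity scores by weighted restricted least squares
#'
#' Regresses each query cell's rank profile on the reference cell-type
#' predictors under the constraints \eqn{\beta_k \ge 0} and
#' \eqn{\sum_k \beta_k \le 1}, minimising
#' \eqn{\sum_g h_g (x_g - \sum_k \beta_k r_{gk})^2} where the per-gene
#' weights \eqn{h_g} (typically the atlas Hellinger scores) emphasise genes
#' that discriminate cell types. The coefficient vector is a continuum
#' identity: mass can spread over several types for transitional or novel
#' states, so the full row should always be inspected, not only the
#' arg-max.
#'
#' In `"subcluster_medoid"` mode each type's predictor column is the
#' query cell's nearest medoid of that type, measured by Euclidean distance
#' in atlas PC space, which requires `query_scores`.
#'
#' @param query_ranked genes x cells rank-transformed query matrix
#'   (typically `projection$query_ranked`).
#' @param predictors an `identity_predictors` object.
#' @param weights non-negative per-gene weights named by gene (default: all
#'   ones); all-zero weights are an error. Scores are invariant to positive
#'   rescaling of the weights.
#' @param query_scores cells x n_pc matrix of projected query scores;
#'   required in medoid mode.
#' @return An object of class `identity_scores`: `beta` (cells x types),
#'   `residual_norm` (weighted residual norm per cell) and
#'   `predictors_used` (cells x types medoid ids, medoid mode only).
#' @export
capybara_score <- function(query_ranked, predictors, weights = NULL,
                           query_scores = NULL) {
  stopifnot(inherits(predictors, "identity_predictors"))
  query_ranked <- as_expr(query_ranked)
  genes <- intersect(predictors$genes, rownames(query_ranked))
  if (length(genes) == 0L) stop("predictors and query share no genes")
  x <- unclass(query_ranked)[genes, , drop = FALSE]
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(genes)), genes)
  }
  w <- weights[genes]
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative for all genes")
  if (sum(w) == 0) stop("all gene weights are zero")
  types <- predictors$types
  n_cell <- ncol(x)
  beta <- matrix(0, n_cell, length(types),
                 dimnames = list(colnames(x), types))
  resid <- numeric(n_cell)
  used <- NULL

  if (predictors$mode == "type_mean") {
    R <- vapply(types, function(ty) predictors$predictors[[ty]]$profile[genes],
                numeric(length(genes)))
    cond <- kappa(crossprod(R * sqrt(w), R))
    if (is.finite(cond) && cond > 1e10) {
      warning(sprintf("predictors are near-collinear (condition number %.3g)",
                      cond))
    }
    for (i in seq_len(n_cell)) {
      b <- rls_solve(R, x[, i], w)
      beta[i, ] <- b
      resid[i] <- sqrt(sum(w * (x[, i] - R %*% b)^2))
    }
  } else {
    if (is.null(query_scores)) {
      stop("query_scores are required in subcluster_medoid mode ",
           "(nearest medoids are chosen in atlas PC space)")
    }
    if (nrow(query_scores) != n_cell) {
      stop("query_scores rows must match the query cells")
    }
    # nearest medoid of each type, per cell
    pick <- matrix(1L, n_cell, length(types), dimnames = list(NULL, types))
    used <- matrix(NA_character_, n_cell, length(types),
                   dimnames = list(colnames(x), types))
    for (j in seq_along(types)) {
      pd <- predictors$predictors[[types[j]]]
      pc <- pd$pc[, seq_len(min(ncol(pd$pc), ncol(query_scores))),
                  drop = FALSE]
      qs <- query_scores[, seq_len(ncol(pc)), drop = FALSE]
      d2 <- outer(rowSums(qs^2), rowSums(pc^2), "+") - 2 * qs %*% t(pc)
      pick[, j] <- max.col(-d2, ties.method = "first")
      used[, j] <- pd$medoid_ids[pick[, j]]
    }
    # cells sharing a medoid-assignment pattern share a design matrix
    key <- apply(pick, 1L, paste, collapse = ",")
    for (pattern in unique(key)) {
      cells <- which(key == pattern)
      sel <- pick[cells[1L], ]
      R <- vapply(seq_along(types), function(j) {
        predictors$predictors[[types[j]]]$profiles[genes, sel[j]]
      }, numeric(length(genes)))
      for (i in cells) {
        b <- rls_solve(R, x[, i], w)
        beta[i, ] <- b
        resid[i] <- sqrt(sum(w * (x[, i] - R %*% b)^2))
      }
    }
  }
  structure(list(beta = beta, residual_norm = resid,
                 predictors_used = used),
            class = "identity_scores")
}

#' @export
print.identity_scores <- function(x, ...) {
  cat(sprintf("<identity_scores> %d cells x %d types; mean top score %.3f\n",
              nrow(x$beta), ncol(x$beta),
              mean(apply(x$beta, 1L, max))))
  invisible(x)
}
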