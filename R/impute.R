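#' k-nearest-neighbour graph of query cells
#'
#' Computes exact Euclidean k-nearest neighbours between cells in the top
#' principal components of the query (dimension reduction acts as a global
#' noise filter before distance calculation). Each cell's first neighbour
#' is the cell itself at distance zero; the remaining neighbours are ordered
#' by distance with index-stable tie-breaking. Duplicate cells are allowed
#' (zero distances).
#'
#' @param query genes x cells matrix of normalized expression.
#' @param kappa neighbourhood size including self (>= 2, <= number of
#'   cells).
#' @param n_pc_graph number of query PCs used for distances (default 30,
#'   capped at what the data allow).
#' @return List with `idx` (cells x kappa neighbour indices, first column
#'   the cell itself) and `dist` (matching Euclidean distances, first
#'   column 0).
#' @export
knn_graph <- function(query, kappa = 30L, n_pc_graph = 30L) {
  query <- as_expr(query)
  n <- ncol(query)
  if (kappa < 2L) stop("kappa must be at least 2")
  if (kappa > n) stop("kappa (", kappa, ") exceeds the number of cells (",
                      n, ")")
  x <- t(unclass(query))
  n_pc_graph <- min(n_pc_graph, nrow(x) - 1L, ncol(x))
  if (n_pc_graph >= 1L && n_pc_graph < ncol(x)) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pc_graph)
    x <- pc$x
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- 0
  idx <- matrix(0L, n, kappa)
  dst <- matrix(0, n, kappa)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n), method = "radix")
    ord <- c(i, ord[ord != i]) # self first even under zero-distance ties
    idx[i, ] <- ord[seq_len(kappa)]
    dst[i, ] <- d[i, idx[i, ]]
  }
  list(idx = idx, dist = dst)
}

#' Distance beyond the nearest neighbour
#'
#' Converts raw neighbour distances into the per-cell pseudo-metric
#' \eqn{d_{c_i}(c_i, c_{ij}) = \max(0, d(c_i, c_{ij}) - d(c_i, c_{i2}))},
#' where \eqn{c_{i2}} is the nearest non-self neighbour. Subtracting the
#' common local scale guarantees every cell connects to its nearest
#' neighbour and counteracts the curse of dimensionality, under which
#' distances to all neighbours look alike.
#'
#' @param raw_dist cells x kappa matrix of ascending neighbour distances,
#'   first column 0 (self), as from [knn_graph()].
#' @return Matrix of the same shape with scaled distances (first two
#'   columns 0).
#' @export
scale_distances <- function(raw_dist) {
  raw_dist <- as.matrix(raw_dist)
  if (ncol(raw_dist) < 2L) stop("need at least two neighbours per cell")
  pmax(raw_dist - raw_dist[, 2L], 0)
}

# Bandwidth such that the kernel at the kappa-th neighbour equals
# log(kappa/(kappa-1)); natural log, which lies in (0,1) for kappa >= 2.
kernel_bandwidth <- function(d_kappa, kappa, floor = 1e-12) {
  target <- log(kappa / (kappa - 1))
  sigma <- d_kappa / sqrt(-log(target))
  pmax(sigma, floor)
}

#' Adaptive Gaussian kernel affinities
#'
#' Builds the asymmetric weighted adjacency
#' \eqn{W^{asy}_{ij} = \exp(-(d_{c_i}(c_i,c_j)/\sigma_{c_i})^2)} for
#' \eqn{c_j} in the neighbourhood of \eqn{c_i} (zero outside). The per-cell
#' bandwidth \eqn{\sigma_{c_i}} is fixed by requiring the kernel at the
#' \eqn{\kappa}-th neighbour to equal \eqn{\log(\kappa/(\kappa-1))}: every
#' cell communicates with its farthest retained neighbour at the same fixed
#' probability, so affinities are defined irrespective of local sampling
#' density. When a cell's scaled distance to its \eqn{\kappa}-th neighbour
#' is zero the bandwidth is floored and all in-neighbourhood affinities
#' become 1.
#'
#' @param graph list with `idx` and scaled `dist` (see [knn_graph()],
#'   [scale_distances()]); `dist` here must be the scaled distances.
#' @param kappa neighbourhood size (>= 2).
#' @param sigma_floor minimum bandwidth (default 1e-12).
#' @return List with `W_asy` (cells x cells dense matrix, entries in
#'   \[0, 1\], unit diagonal) and `sigma` (per-cell bandwidth).
#' @export
adaptive_kernel <- function(graph, kappa, sigma_floor = 1e-12) {
  if (kappa < 2L) {
    stop("kappa must be at least 2 for the bandwidth identity to be defined")
  }
  idx <- graph$idx
  sd <- graph$dist
  n <- nrow(idx)
  sigma <- kernel_bandwidth(sd[, ncol(sd)], kappa, floor = sigma_floor)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, idx[i, ]] <- exp(-(sd[i, ] / sigma[i])^2)
  }
  list(W_asy = w, sigma = sigma)
}

#' Fuzzy Jaccard symmetrisation of the affinity graph
#'
#' Symmetrises the asymmetric affinities by the average of the two
#' directed weights multiplied by a Fuzzy Jaccard Index between the two
#' cells' neighbourhood affinity rows, with a product t-norm in the
#' numerator and a probabilistic t-conorm in the denominator:
#' \deqn{W_{ij} = \frac{W^{asy}_{ij} + W^{asy}_{ji}}{2} \cdot
#'   \frac{\sum_k W^{asy}_{ik} W^{asy}_{jk}}
#'        {\sum_k (W^{asy}_{ik} + W^{asy}_{jk} - W^{asy}_{ik} W^{asy}_{jk})}}
#' The overlap factor lies in \[0, 1\] and down-weights connections between
#' cells that do not share neighbourhoods, which protects small cell
#' populations from being absorbed by large ones during diffusion. Pairs
#' with a zero denominator (no neighbourhood mass in either row) get zero
#' affinity.
#'
#' @param W_asy asymmetric affinity matrix with entries in \[0, 1\].
#' @return Symmetric non-negative affinity matrix `W`.
#' @export
fuji_symmetrize <- function(W_asy) {
  a <- as.matrix(W_asy)
  if (nrow(a) != ncol(a)) stop("W_asy must be square")
  num <- tcrossprod(a)                       # sum_k a_ik a_jk
  r <- rowSums(a)
  den <- outer(r, r, "+") - num              # probabilistic t-conorm sum
  fuji <- ifelse(den > 0, num / den, 0)
  w <- ((a + t(a)) / 2) * fuji
  (w + t(w)) / 2 # exact symmetry against floating-point asymmetry
}

#' Laplace-Beltrami diffusion operator
#'
#' From a symmetric affinity matrix, computes kernel volumes
#' \eqn{\bar q_i = \sum_j W_{ij}}, the density-normalised kernel
#' \eqn{\bar W_{ij} = W_{ij} / (\bar q_i \bar q_j)} (Laplace-Beltrami
#' normalisation, making the diffusion geometry insensitive to sampling
#' density), and the row-stochastic Markov operator
#' \eqn{P_{ij} = \bar W_{ij} / \sum_j \bar W_{ij}}. Eigenpairs are obtained
#' from the symmetric conjugate of `P`, guaranteeing a real spectrum with
#' \eqn{\lambda_0 = 1}; \eqn{\lambda_1 < 1} exactly when the graph is
#' connected.
#'
#' @param W symmetric non-negative affinity matrix with positive row sums.
#' @param eigen compute the eigendecomposition (default TRUE; skip for
#'   speed when only `P` is needed).
#' @return List with `q_bar`, `W_bar`, `P`, and when requested `eigvals`
#'   (descending) and `eigvecs` (columns are left eigenvectors of `P`).
#' @export
diffusion_operator <- function(W, eigen = TRUE) {
  w <- as.matrix(W)
  if (max(abs(w - t(w))) > 0) stop("W must be symmetric")
  q_bar <- rowSums(w)
  if (any(q_bar <= 0)) {
    bad <- which(q_bar <= 0)
    stop("cell(s) with zero kernel volume (isolated): ",
         paste(if (is.null(rownames(w))) bad else rownames(w)[bad],
               collapse = ", "))
  }
  w_bar <- w / outer(q_bar, q_bar)
  d <- rowSums(w_bar)
  p <- w_bar / d
  out <- list(q_bar = q_bar, W_bar = w_bar, P = p)
  if (eigen) {
    # symmetric conjugate M = D^{1/2} P D^{-1/2} shares P's eigenvalues
    s <- sqrt(d)
    m <- w_bar / outer(s, s)
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    out$eigvals <- e$values
    out$eigvecs <- e$vectors * s # left eigenvectors psi = D^{1/2} v
  }
  out
}

#' Build the full diffusion graph of a query
#'
#' Convenience wrapper chaining [knn_graph()], [scale_distances()],
#' [adaptive_kernel()], [fuji_symmetrize()] and [diffusion_operator()].
#' The `distance_scaling` and `fuji` switches exist to ablate the two
#' robustness ingredients (plain Gaussian kernel on raw distances,
#' averaged symmetrisation), chiefly for method comparison.
#'
#' @inheritParams knn_graph
#' @param distance_scaling apply the beyond-nearest-neighbour pseudo-metric
#'   (default TRUE).
#' @param fuji apply Fuzzy Jaccard symmetrisation (default TRUE); when
#'   FALSE the graph is symmetrised by the plain average
#'   `(W_asy + t(W_asy))/2`.
#' @param eigen passed to [diffusion_operator()].
#' @return An object of class `diffusion_graph`: the fields of all
#'   intermediate steps (`knn`, `raw_dist`, `scaled_dist`, `sigma`,
#'   `W_asy`, `W`, `q_bar`, `W_bar`, `P`, optional eigenpairs) plus
#'   `kappa`.
#' @export
diffusion_graph <- function(query, kappa = 30L, n_pc_graph = 30L,
                            distance_scaling = TRUE, fuji = TRUE,
                            eigen = TRUE) {
  g <- knn_graph(query, kappa = kappa, n_pc_graph = n_pc_graph)
  sd <- if (distance_scaling) scale_distances(g$dist) else g$dist
  ak <- adaptive_kernel(list(idx = g$idx, dist = sd), kappa = kappa)
  w <- if (fuji) {
    fuji_symmetrize(ak$W_asy)
  } else {
    (ak$W_asy + t(ak$W_asy)) / 2
  }
  op <- diffusion_operator(w, eigen = eigen)
  structure(c(list(kappa = kappa, knn = g$idx, raw_dist = g$dist,
                   scaled_dist = sd, sigma = ak$sigma, W_asy = ak$W_asy,
                   W = w), op),
            class = "diffusion_graph")
}

#' @export
print.diffusion_graph <- function(x, ...) {
  cat(sprintf("<diffusion_graph> %d cells, kappa = %d\n",
              nrow(x$P), x$kappa))
  invisible(x)
}

#' Graph-diffusion imputation
#'
#' Imputes each cell as the transition-probability-weighted average of the
#' profiles in its diffusion neighbourhood:
#' \eqn{\bar x_i = \sum_j (P^t)_{ij} x_j}. `t` is the diffusion time: 0
#' returns the input unchanged, larger values smooth more strongly (and
#' risk over-imputation). Since rows of \eqn{P^t} are convex weights,
#' imputed values stay within the per-gene range of the original cells,
#' and disconnected graph components never exchange information.
#'
#' @param query genes x cells matrix.
#' @param P row-stochastic diffusion operator (cells x cells), or a
#'   `diffusion_graph`.
#' @param t non-negative integer diffusion time (default 3).
#' @return An `expr_mat` of imputed values, same dimnames and unit as the
#'   input.
#' @export
impute_expression <- function(query, P, t = 3L) {
  query <- as_expr(query)
  if (inherits(P, "diffusion_graph")) P <- P$P
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != round(t)) {
    stop("t must be a non-negative integer (powering is repeated application)")
  }
  t <- as.integer(t)
  x <- unclass(query)
  if (ncol(x) != nrow(P)) stop("query and P dimensions do not match")
  if (t == 0L) return(query)
  pt <- P
  if (t > 1L) for (i in seq_len(t - 1L)) pt <- pt %*% P
  out <- x %*% t(pt) # out[, i] = sum_j (P^t)_ij x_j
  dimnames(out) <- dimnames(x)
  expr_matrix(pmax(out, 0), unit = expr_unit(query))
}

# connected components of the support of a symmetric affinity matrix
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Choose the neighbourhood size kappa
#'
#' Two data-driven alternatives to the default \eqn{\kappa = 30}:
#' `"connectivity"` returns the smallest \eqn{\kappa} whose symmetrised
#' graph is a single connected component (appropriate when no population is
#' believed functionally isolated); `"sparsity"` returns the smallest
#' \eqn{\kappa} such that one diffusion step (`t = 1`) brings the fraction
#' of zero entries down to `target` (default 0.25), avoiding any tuning of
#' the diffusion time. Both assume the criterion is monotone in
#' \eqn{\kappa} and use binary search. If the sparsity target is not
#' reachable even at \eqn{\kappa = N}, `N` is returned with a warning.
#'
#' @param query genes x cells matrix.
#' @param mode `"connectivity"` or `"sparsity"`.
#' @param t diffusion steps used in sparsity mode (default 1).
#' @param target sparsity target (default 0.25).
#' @param n_pc_graph PCs for the graph distances (see [knn_graph()]).
#' @return The selected integer kappa.
#' @export
choose_kappa <- function(query, mode = c("connectivity", "sparsity"),
                         t = 1L, target = 0.25, n_pc_graph = 30L) {
  mode <- match.arg(mode)
  query <- as_expr(query)
  n <- ncol(query)
  ok <- function(kappa) {
    g <- diffusion_graph(query, kappa = kappa, n_pc_graph = n_pc_graph,
                         eigen = FALSE)
    if (mode == "connectivity") {
      max(graph_components(g$W)) == 1L
    } else {
      mean(unclass(impute_expression(query, g$P, t = t)) == 0) <= target
    }
  }
  lo <- 2L
  hi <- n
  if (ok(lo)) return(lo)
  if (!ok(hi)) {
    if (mode == "sparsity") {
      warning("sparsity target ", target, " unreachable even at kappa = N; ",
              "returning N = ", n)
      return(hi)
    }
    stop("graph not connected even at kappa = N") # cannot happen: complete
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Shrink imputed profiles back toward the originals
#'
#' Guards against over-imputation by taking, for each cell, a weighted
#' average of its original and imputed profile:
#' `out_i = alpha_i * imputed_i + (1 - alpha_i) * original_i`. The weight
#' follows two principles: retained post-imputation variance up-weights the
#' imputed profile, while large per-cell imputation strength (relative
#' deviation between imputed and original) up-weights the original.
#' Concretely `alpha_i = v / (v + s_i)` with
#' `v = min(1, totalVar(imputed) / totalVar(original))` (total variance =
#' sum of per-gene variances across cells) and
#' `s_i = ||imputed_i - original_i|| / ||original_i||`. A cell whose
#' original profile has zero norm gets `alpha_i = v`.
#'
#' @param original genes x cells matrix before imputation.
#' @param imputed conformable imputed matrix.
#' @return An `expr_mat` of scaled profiles plus attribute `"alpha"` with
#'   the per-cell weights.
#' @export
post_scale <- function(original, imputed) {
  original <- as_expr(original)
  imputed <- as_expr(imputed)
  x <- unclass(original)
  y <- unclass(imputed)
  if (!all(dim(x) == dim(y))) stop("original and imputed must be conformable")
  tv <- function(m) sum(apply(m, 1L, stats::var))
  tv_x <- tv(x)
  v <- if (tv_x > 0) min(1, tv(y) / tv_x) else 1
  norm_x <- sqrt(colSums(x^2))
  dev <- sqrt(colSums((y - x)^2))
  s <- ifelse(norm_x > 0, dev / pmax(norm_x, .Machine$double.xmin), 0)
  denom <- v + s
  alpha <- ifelse(denom > 0, v / denom, 0)
  alpha[norm_x == 0] <- v
  out <- sweep(y, 2L, alpha, "*") + sweep(x, 2L, 1 - alpha, "*")
  dimnames(out) <- dimnames(x)
  res <- expr_matrix(out, unit = expr_unit(original))
  attr(res, "alpha") <- alpha
  res
}
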