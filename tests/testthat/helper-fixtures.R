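# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small paired atlas/query simulation reused across files.
toy_sim <- function() {
  cached("toy_sim", {
    cfg <- sim_config(n_types = 3L, genes = 300L, marker_frac = 0.05,
                      bulk_reps_per_type = 8L, cells_per_type = 40L,
                      library_size = 1500L, seed = 42L)
    atl <- simulate_atlas(cfg)
    qry <- simulate_query(cfg, atl$means)
    atlas <- fit_atlas(atl$expr, atl$labels, n_genes = 200L, n_pc = 5L)
    list(cfg = cfg, atl = atl, qry = qry, atlas = atlas)
  })
}

# Euclidean projection onto {b : b >= 0, sum(b) <= 1}.
proj_capped_simplex <- function(b) {
  b <- pmax(b, 0)
  if (sum(b) <= 1) return(b)
  # project onto the simplex sum(b) = 1 (sort-and-threshold)
  u <- sort(b, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(b - theta, 0)
}

# Projected-gradient oracle for the weighted restricted least squares:
# min sum_g w_g (x_g - sum_k b_k R_gk)^2  s.t.  b >= 0, sum(b) <= 1.
pg_rls <- function(R, x, w, iters = 200000L) {
  k <- ncol(R)
  hw <- R * w
  Q <- crossprod(hw, R)
  c0 <- drop(crossprod(hw, x))
  step <- 1 / (2 * max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values))
  b <- rep(1 / (k + 1), k)
  for (i in seq_len(iters)) {
    g <- 2 * (Q %*% b - c0)
    b <- proj_capped_simplex(b - step * drop(g))
  }
  b
}
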