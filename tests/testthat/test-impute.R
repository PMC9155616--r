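test_that("kNN lists start at self and match a brute-force search", {
  set.seed(21)
  pts <- matrix(c(0, 0, 1, 0, 0, 1.5, 4, 4, 4.2, 4), 2, 5)
  q <- expr_matrix(pts + 10, unit = "cpm") # shift keeps values positive
  g <- knn_graph(q, kappa = 4, n_pc_graph = 2)
  expect_equal(g$idx[, 1], 1:5)
  expect_equal(g$dist[, 1], rep(0, 5))
  d <- as.matrix(dist(t(pts)))
  for (i in 1:5) {
    ord <- order(d[i, ]); ord <- c(i, ord[ord != i])
    expect_equal(g$idx[i, ], ord[1:4])
    expect_equal(g$dist[i, ], unname(d[i, g$idx[i, ]]), tolerance = 1e-12)
  }

  # duplicated cells are each other's second neighbour at distance 0
  dup <- expr_matrix(cbind(c(1, 2), c(1, 2), c(5, 9)), unit = "cpm")
  gd <- knn_graph(dup, kappa = 2, n_pc_graph = 2)
  expect_equal(gd$idx[1, ], c(1L, 2L))
  expect_equal(gd$idx[2, ], c(2L, 1L))
  expect_equal(gd$dist[1, 2], 0)

  expect_error(knn_graph(dup, kappa = 9), "exceeds")
  expect_error(knn_graph(dup, kappa = 1), "at least 2")
})

test_that("distance scaling subtracts the nearest non-self distance", {
  expect_equal(scale_distances(rbind(c(0, 2, 3, 5))),
               rbind(c(0, 0, 1, 3)))
  expect_equal(scale_distances(rbind(c(0, 4, 4, 4))),
               rbind(c(0, 0, 0, 0)))
  # ties with the nearest neighbour clamp to zero, never negative
  out <- scale_distances(rbind(c(0, 2, 2, 2.5)))
  expect_equal(out, rbind(c(0, 0, 0, 0.5)))
  expect_true(all(out >= 0))
})

test_that("adaptive kernel satisfies the bandwidth identity", {
  # kappa = 4, scaled distance 3 to the 4th neighbour
  sd <- rbind(c(0, 1, 2, 3), c(0, 0.5, 1, 2), c(0, 1, 1, 1), c(0, 2, 2, 4))
  idx <- rbind(c(1, 2, 3, 4), c(2, 1, 3, 4), c(3, 1, 2, 4), c(4, 1, 2, 3))
  ak <- adaptive_kernel(list(idx = idx, dist = sd), kappa = 4)
  expect_equal(ak$sigma[1], 3 / sqrt(-log(log(4 / 3))), tolerance = 1e-12)
  expect_equal(ak$sigma[1], 2.688, tolerance = 1e-3)
  # substituting sigma back: kernel at the kappa-th neighbour = ln(k/(k-1))
  expect_equal(exp(-(sd[1, 4] / ak$sigma[1])^2), log(4 / 3),
               tolerance = 1e-10)
  expect_equal(exp(-(sd[2, 4] / ak$sigma[2])^2), log(4 / 3),
               tolerance = 1e-10)
  # self affinity 1; zero outside the neighbourhood
  expect_equal(diag(ak$W_asy), rep(1, 4))
  expect_true(all(ak$W_asy >= 0 & ak$W_asy <= 1))

  # zero distance to the kappa-th neighbour: floored bandwidth, kernels 1
  akz <- adaptive_kernel(list(idx = idx, dist = sd * 0), kappa = 4)
  expect_true(all(akz$W_asy[1, 1:4] == 1))
  expect_error(adaptive_kernel(list(idx = idx, dist = sd), kappa = 1),
               "at least 2")
})

test_that("Fuzzy Jaccard symmetrisation matches the 2-cell closed form", {
  for (ab in list(c(0.3, 0.7), c(1, 1), c(0.2, 0.2))) {
    w <- fuji_symmetrize(rbind(c(1, ab[1]), c(ab[2], 1)))
    expect_equal(w[1, 2], mean(ab)^2, tolerance = 1e-12)
  }
  expect_equal(fuji_symmetrize(rbind(c(1, 0), c(0, 1)))[1, 2], 0)
  # zero denominator pair maps to zero affinity
  expect_equal(fuji_symmetrize(matrix(0, 2, 2)), matrix(0, 2, 2))
  # exact symmetry for arbitrary input
  set.seed(8)
  a <- matrix(runif(100), 10, 10)
  w <- fuji_symmetrize(a)
  expect_identical(w, t(w))
  expect_true(all(w >= 0))
})

test_that("diffusion operator is Markov with the documented hand values", {
  op <- diffusion_operator(rbind(c(1, 1), c(1, 1)))
  expect_equal(op$q_bar, c(2, 2))
  expect_equal(op$W_bar, matrix(0.25, 2, 2))
  expect_equal(op$P, matrix(0.5, 2, 2))
  expect_equal(op$eigvals[1], 1, tolerance = 1e-12)

  # block-diagonal affinity: eigenvalue 1 with multiplicity 2
  w <- matrix(0, 4, 4)
  w[1:2, 1:2] <- c(1, 0.5, 0.5, 1)
  w[3:4, 3:4] <- c(1, 0.8, 0.8, 1)
  op2 <- diffusion_operator(w)
  expect_equal(sum(op2$eigvals > 1 - 1e-10), 2L)
  expect_true(all(abs(rowSums(op2$P) - 1) < 1e-12))
  expect_equal(op2$P[1:2, 3:4], matrix(0, 2, 2))

  expect_error(diffusion_operator(diag(c(1, 1, 0))), "isolated")
  expect_error(diffusion_operator(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("imputation averages within components and preserves hulls", {
  # uniform P: both cells imputed to the two-cell average
  x <- expr_matrix(cbind(c(4, 0), c(0, 2)), unit = "cpm")
  p <- matrix(0.5, 2, 2)
  out <- impute_expression(x, p, t = 1)
  expect_equal(unclass(out), cbind(c(2, 1), c(2, 1)), ignore_attr = TRUE)
  # t = 0 is the identity
  expect_equal(unclass(impute_expression(x, p, t = 0)), unclass(x))
  expect_error(impute_expression(x, p, t = 1.5), "integer")

  # two disconnected components never exchange information
  set.seed(31)
  xx <- matrix(rpois(80, 8), 10, 8)
  pblk <- matrix(0, 8, 8)
  pblk[1:4, 1:4] <- 0.25
  pblk[5:8, 5:8] <- 0.25
  base <- unclass(impute_expression(expr_matrix(xx, unit = "cpm"),
                                    pblk, t = 3))
  xx2 <- xx
  xx2[, 5:8] <- xx2[, 5:8] + 100
  pert <- unclass(impute_expression(expr_matrix(xx2, unit = "cpm"),
                                    pblk, t = 3))
  expect_equal(pert[, 1:4], base[, 1:4])

  # convex-hull preservation on a real graph for several diffusion times
  fx <- toy_sim()
  norm <- normalize_library(fx$qry$expr)
  g <- diffusion_graph(norm, kappa = 10, eigen = FALSE)
  lo <- apply(unclass(norm), 1, min)
  hi <- apply(unclass(norm), 1, max)
  for (t in c(1, 3, 10)) {
    imp <- unclass(impute_expression(norm, g, t = t))
    expect_true(all(imp >= lo - 1e-9 & imp <= hi + 1e-9))
  }
})

test_that("diffusion smoothing reduces variance monotonically in t", {
  set.seed(41)
  x <- expr_matrix(matrix(rpois(600, 6) + 1, 20, 30), unit = "cpm")
  g <- diffusion_graph(x, kappa = 30, eigen = TRUE) # complete: connected
  expect_lt(g$eigvals[2], 1)
  tv <- sapply(0:4, function(t) {
    sum(apply(unclass(impute_expression(x, g, t = t)), 1, var))
  })
  expect_true(all(diff(tv) <= 1e-10))
})

test_that("imputation is equivariant under cell permutation", {
  fx <- toy_sim()
  norm <- unclass(normalize_library(fx$qry$expr))[, 1:40]
  perm <- sample(40)
  g1 <- diffusion_graph(expr_matrix(norm, unit = "cpm"), kappa = 8,
                        eigen = FALSE)
  g2 <- diffusion_graph(expr_matrix(norm[, perm], unit = "cpm"), kappa = 8,
                        eigen = FALSE)
  i1 <- unclass(impute_expression(expr_matrix(norm, unit = "cpm"), g1, t = 2))
  i2 <- unclass(impute_expression(expr_matrix(norm[, perm], unit = "cpm"),
                                  g2, t = 2))
  expect_equal(i2, i1[, perm], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("kappa selection finds connectivity and sparsity thresholds", {
  # two far-apart duplicate-pair blobs: graph connects at kappa = 3
  pts <- cbind(c(0, 0), c(0, 0), c(50, 50), c(50, 50)) + 1
  q <- expr_matrix(pts, unit = "cpm")
  k <- choose_kappa(q, "connectivity", n_pc_graph = 2)
  # oracle: exhaustive component search over all kappa
  connected_at <- sapply(2:4, function(kk) {
    g <- diffusion_graph(q, kappa = kk, n_pc_graph = 2, eigen = FALSE)
    igraph::count_components(
      igraph::graph_from_adjacency_matrix(g$W > 0, mode = "undirected")) == 1
  })
  expect_equal(k, (2:4)[which(connected_at)[1]])

  # mutually equidistant cells connect at kappa = 2
  tri <- expr_matrix(cbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)) + 1,
                     unit = "cpm")
  expect_equal(choose_kappa(tri, "connectivity", n_pc_graph = 2), 2L)

  # fully dense query is already below the sparsity target at kappa = 2
  dense <- expr_matrix(matrix(runif(60) + 1, 6, 10), unit = "cpm")
  expect_equal(choose_kappa(dense, "sparsity"), 2L)

  # unreachable sparsity target returns N with a warning
  allzero_gene <- rbind(matrix(runif(30) + 1, 3, 10), 0)
  expect_warning(kN <- choose_kappa(expr_matrix(allzero_gene, unit = "cpm"),
                                    "sparsity", target = 0.01),
                 "unreachable")
  expect_equal(kN, 10L)
})

test_that("post-imputation scaling interpolates as documented", {
  set.seed(51)
  x <- matrix(rpois(60, 10) + 1, 6, 10)
  ex <- expr_matrix(x, unit = "cpm")
  # imputed = original: output = original
  expect_equal(unclass(post_scale(ex, ex)), x, ignore_attr = TRUE)
  # variance annihilated (v -> 0): output -> original
  flat <- matrix(rowMeans(x), 6, 10)
  ps <- post_scale(ex, expr_matrix(flat, unit = "cpm"))
  expect_equal(attr(ps, "alpha"), rep(0, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(ps), x, ignore_attr = TRUE)
  # alpha follows v / (v + s_i); with v = 1 and s_i = 1 this is the midpoint
  orig <- cbind(c(2, 0, 0), c(0, 3, 0))
  imp <- cbind(c(2, 2, 0), c(0, 3, 3)) # deviation norm = cell norm -> s = 1
  v_manual <- min(1, sum(apply(imp, 1, var)) / sum(apply(orig, 1, var)))
  ps2 <- post_scale(expr_matrix(orig, unit = "cpm"),
                    expr_matrix(imp, unit = "cpm"))
  s1 <- sqrt(sum((imp[, 1] - orig[, 1])^2)) / sqrt(sum(orig[, 1]^2))
  expect_equal(unname(attr(ps2, "alpha")[1]), v_manual / (v_manual + s1),
               tolerance = 1e-12)
})
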