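test_that("rank transformation yields fractional average-tie ranks", {
  out <- rank_transform(matrix(c(0, 0, 5, 10), 4, 1))
  expect_equal(as.numeric(out), c(0.375, 0.375, 0.75, 1.0))
  expect_equal(expr_unit(out), "rank")

  const <- rank_transform(matrix(7, 4, 1))
  expect_equal(as.numeric(const), rep(0.625, 4))

  # invariance under strictly increasing per-column maps
  a <- rank_transform(matrix(c(1, 2, 3), 3, 1))
  b <- rank_transform(matrix(c(1, 4, 9), 3, 1))
  expect_equal(unclass(a), unclass(b))

  expect_error(rank_transform(matrix(numeric(0), 0, 0)), "empty")
  expect_error(rank_transform(matrix(c(-1, 2), 2, 1)), "non-negative")
})

test_that("rank transformation is idempotent on tie-free data", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(sample(1000, 60), 20, 3)
    r1 <- rank_transform(x)
    expect_equal(unclass(rank_transform(r1)), unclass(r1))
  }
})

test_that("Hellinger scores match closed forms and stay in [0, 1]", {
  # identical in/out rank distributions in every class -> 0
  ranked <- expr_matrix(matrix(rep(c(0.1, 0.6), 4), nrow = 1), unit = "rank")
  expect_equal(unname(hd_score(ranked, rep(c("A", "B"), each = 4))), 0)

  # disjoint bins -> 1
  ranked <- expr_matrix(matrix(c(0.05, 0.08, 0.95, 0.97), nrow = 1),
                        unit = "rank")
  expect_equal(unname(hd_score(ranked, c("A", "A", "B", "B"))), 1)

  # p = (1, 0) vs q = (0.5, 0.5) over 2 bins: H = sqrt(1 - sqrt(0.5))
  ranked <- expr_matrix(matrix(c(0.3, 0.4, 0.2, 0.45, 0.7, 0.9), nrow = 1),
                        unit = "rank")
  h <- hd_score(ranked, c("A", "A", "B", "B", "B", "B"), n_bins = 2L)
  expect_equal(unname(h), sqrt(1 - sqrt(0.5)), tolerance = 1e-12)

  expect_error(hd_score(ranked, rep("A", 6)), "two classes")
  set.seed(3)
  rr <- rank_transform(matrix(rpois(400, 10), 20, 20))
  hh <- hd_score(rr, rep(c("A", "B"), 10))
  expect_true(all(hh >= 0 & hh <= 1))
})

test_that("gene selection keeps top scores with stable id tie-breaks", {
  ranked <- expr_matrix(matrix(0.5, 3, 4,
                               dimnames = list(c("gA", "gB", "gC"), NULL)),
                        unit = "rank")
  hd <- c(gA = 0.9, gB = 0.2, gC = 0.5)
  expect_equal(select_genes(ranked, hd, 2), c("gA", "gC"))
  expect_setequal(select_genes(ranked, hd, 3), c("gA", "gB", "gC"))
  # tie at the cutoff: lexicographically earlier id wins
  hd2 <- c(gA = 0.9, gB = 0.5, gC = 0.5)
  expect_equal(select_genes(ranked, hd2, 2), c("gA", "gB"))
  expect_error(select_genes(ranked, hd, 0), "positive")
  expect_error(select_genes(ranked, hd, 5), "exceeds")
})

test_that("atlas PCA is self-consistent and matches a covariance oracle", {
  set.seed(5)
  x <- matrix(rpois(200, 20), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  labels <- rep(c("A", "B"), each = 5)
  x[1:5, labels == "A"] <- x[1:5, labels == "A"] + 50
  atlas <- fit_atlas(x, labels, n_genes = 20, n_pc = 4)

  # loadings orthonormal; scores centred; eigenvalues descending
  expect_equal(crossprod(atlas$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(atlas$scores))), 1e-8)
  expect_true(all(diff(atlas$eigenvalues) <= 1e-12))

  # projecting the reference's own centred ranks through the loadings
  # reproduces the scores
  centred <- unclass(atlas$ranked) - atlas$centering_means
  expect_equal(t(centred) %*% atlas$loadings, atlas$scores,
               tolerance = 1e-10, ignore_attr = TRUE)

  # trace conservation with all components kept
  full <- fit_atlas(x, labels, n_genes = 20, n_pc = 9)
  centred <- unclass(full$ranked) - full$centering_means
  expect_equal(sum(full$eigenvalues), sum(apply(centred, 1, var)),
               tolerance = 1e-6)

  # independent oracle: eigendecomposition of the sample covariance of an
  # independently rank-transformed toy
  toy <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  at <- fit_atlas(toy, c("A", "B", "B"), n_genes = 4, n_pc = 2)
  rk <- apply(toy, 2, rank) / 4
  ce <- rk - rowMeans(rk)
  ev <- eigen(stats::cov(t(ce)), symmetric = TRUE)
  oracle_scores <- t(ce) %*% ev$vectors[, 1:2]
  expect_equal(abs(unclass(at$scores)), abs(oracle_scores),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(at$eigenvalues, ev$values[1:2], tolerance = 1e-8)
})

test_that("atlas fit is invariant to sample order up to loading signs", {
  fx <- toy_sim()
  perm <- sample(ncol(fx$atl$expr))
  a2 <- fit_atlas(unclass(fx$atl$expr)[, perm], fx$atl$labels[perm],
                  n_genes = 200L, n_pc = 5L)
  expect_equal(a2$genes, fx$atlas$genes)
  expect_equal(abs(unclass(a2$scores)[colnames(fx$atl$expr), ]),
               abs(unclass(fx$atlas$scores)), tolerance = 1e-8)
})

test_that("requesting more components than the matrix rank names the maximum", {
  x <- matrix(rpois(40, 20), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_error(fit_atlas(x, c("A", "A", "B", "B"), n_genes = 10, n_pc = 9),
               "attainable maximum is")
})
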