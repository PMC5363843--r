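# Dissimilarity, PCoA, Procrustes/PROTEST and the species-subset null.

test_that("dissimilarities match plug-in arithmetic", {
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1))
  expect_equal(as.numeric(dissimilarity(m, "bray")), 1 / 3)
  expect_equal(as.numeric(dissimilarity(m, "jaccard")), 1 / 3)
  ident <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.numeric(dissimilarity(ident, "bray")), 0)
  disj <- rbind(a = c(2, 2, 0, 0), b = c(0, 0, 3, 1))
  expect_equal(as.numeric(dissimilarity(disj, "bray")), 1)
  expect_equal(as.numeric(dissimilarity(disj, "jaccard")), 1)
})

test_that("jaccard is the monotone transform of bray on binary data", {
  # on 0/1 matrices J = 2B / (1 + B), so the two metrics carry the same
  # compositional ranking
  set.seed(5)
  m <- matrix(rbinom(40, 1, 0.5), nrow = 8)
  m[1, ] <- 1  # avoid empty rows
  J <- as.numeric(dissimilarity(m, "jaccard"))
  B <- as.numeric(dissimilarity(m, "bray"))
  expect_equal(J, 2 * B / (1 + B), tolerance = 1e-9)
  expect_equal(order(J), order(B))
})

test_that("all-zero nights are dropped and sparse matrices flagged", {
  m <- rbind(a = c(1, 1), b = c(0, 0), c = c(2, 0), d = c(0, 3))
  d <- dissimilarity(m, "bray")
  expect_equal(attr(d, "dropped_rows"), "b")
  expect_false(attr(d, "degenerate"))
  m2 <- rbind(a = c(1, 1), b = c(0, 0), c = c(0, 0), d = c(0, 0))
  expect_true(attr(dissimilarity(m2, "bray"), "degenerate"))
})

test_that("principal coordinates reproduce Euclidean geometry", {
  set.seed(9)
  pts <- matrix(rnorm(8), ncol = 2,
                dimnames = list(paste0("r", 1:4), NULL))
  d <- dist(pts)
  ord <- suppressWarnings(pcoa_scores(d, n_axes = 5))
  expect_lt(max(abs(as.matrix(dist(ord$scores)) - as.matrix(d))), 1e-8)
  # three equidistant points: simplex has two equal positive axes
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  ord3 <- suppressWarnings(pcoa_scores(d3, n_axes = 5))
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-9)
  expect_lte(ord3$n_axes_used, 2)
  # duplicate rows become coincident points
  m <- rbind(a = c(3, 1, 0), b = c(3, 1, 0), c = c(0, 1, 3),
             d = c(1, 1, 1))
  ordd <- suppressWarnings(pcoa_scores(dissimilarity(m, "bray"), 3))
  expect_lt(sum((ordd$scores["a", ] - ordd$scores["b", ])^2), 1e-12)
})

test_that("Procrustes r is invariant to similarity transforms", {
  set.seed(11)
  X <- matrix(rnorm(12), ncol = 2, dimnames = list(paste0("r", 1:6), NULL))
  self <- procrustes_r(X, X)
  expect_equal(self$m2, 0, tolerance = 1e-12)
  expect_equal(self$r, 1, tolerance = 1e-12)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  Y <- 2 * X %*% R + 5
  rownames(Y) <- rownames(X)
  expect_equal(procrustes_r(X, Y)$r, 1, tolerance = 1e-10)
  Yr <- Y %*% diag(c(1, -1))  # reflection
  rownames(Yr) <- rownames(X)
  expect_equal(procrustes_r(X, Yr)$r, 1, tolerance = 1e-10)
  rownames(Yr) <- rev(rownames(X))
  expect_error(procrustes_r(X, Yr), "labels")
})

test_that("Procrustes m2 matches the brute-force rotation search", {
  # unit square with one displaced corner
  X <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2)
  Y <- X
  Y[2, ] <- Y[2, ] + c(0.3, -0.2)
  rownames(X) <- rownames(Y) <- paste0("r", 1:4)
  expect_equal(procrustes_r(X, Y)$m2, brute_m2(X, Y), tolerance = 1e-6)
  set.seed(13)
  for (i in 1:3) {
    A <- matrix(rnorm(12), ncol = 2)
    B <- matrix(rnorm(12), ncol = 2)
    rownames(A) <- rownames(B) <- paste0("r", 1:6)
    expect_equal(procrustes_r(A, B)$m2, brute_m2(A, B), tolerance = 1e-6)
  }
})

test_that("PROTEST self-comparison attains the minimal p", {
  set.seed(15)
  X <- matrix(rnorm(40), ncol = 2, dimnames = list(paste0("r", 1:20), NULL))
  expect_equal(protest_p(X, X, n_perm = 99, seed = 1), 1 / 100)
  expect_error(protest_p(X, X, n_perm = 0), "n_perm")
})

test_that("schedule congruence is exact for self and padded comparisons", {
  m <- random_matrix(15, 8, lambda = 2, seed = 19)
  sc <- strategy_congruence(m, m, "bray", n_perm = 99, seed = 1)
  expect_equal(sc$r, 1, tolerance = 1e-10)
  expect_false(sc$degenerate)
  # removing an all-zero column cannot change dissimilarities
  m0 <- cbind(m, ghost = 0L)
  expect_equal(strategy_congruence(m0, m, "jaccard", n_perm = 0)$r, 1,
               tolerance = 1e-10)
  # proportional counts give identical Bray-Curtis geometry
  expect_equal(strategy_congruence(m, 3L * m, "bray", n_perm = 0)$r, 1,
               tolerance = 1e-10)
})

test_that("near-empty schedule matrices are flagged degenerate", {
  m <- random_matrix(10, 6, lambda = 2, seed = 23)
  sparse <- m
  sparse[3:10, ] <- 0L
  sc <- strategy_congruence(m, sparse, "bray", n_perm = 0)
  expect_true(sc$degenerate)
  expect_true(is.na(sc$r))
})

test_that("null draws at the full species count are perfect", {
  m <- random_matrix(12, 6, lambda = 2, seed = 29)
  nd <- null_model(m, k = 6, n_draws = 5, metric = "bray", seed = 3)
  expect_true(all(abs(nd$r - 1) < 1e-10))
})

test_that("null congruence increases with subset size", {
  m <- random_matrix(25, 15, lambda = 1.5, seed = 31)
  nd <- null_model(m, k = c(3, 6, 9, 12), n_draws = 80, metric = "bray",
                   n_axes = 4, seed = 7)
  means <- tapply(nd$r, nd$k, mean, na.rm = TRUE)
  expect_gt(cor(as.numeric(names(means)), means, method = "spearman"), 0.9)
})

test_that("null percentiles place known draws sensibly", {
  m <- random_matrix(15, 10, lambda = 2, seed = 37)
  nd <- null_model(m, k = 5, n_draws = 50, metric = "jaccard", seed = 11)
  expect_lt(null_percentile(nd, 0), 0.05)
  expect_gt(null_percentile(nd, 1), 0.9)
})
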