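test_that("a rank-1 truth is recovered up to scale", {
  set.seed(61)
  lam <- c(0.9, 1.1, 0.8, 1.0, 1.2)
  f <- rnorm(200)
  X <- outer(f, lam) + matrix(rnorm(1000, 0, sqrt(0.1)), 200)
  fa <- fit_fa(X, 1)
  cosine <- abs(sum(fa$loadings * lam)) /
    sqrt(sum(fa$loadings^2) * sum(lam^2))
  expect_gt(cosine, 0.99)
  expect_true(all(fa$psi >= 0))
  expect_true(all(diff(fa$ll_trace) > -1e-6))
})

test_that("a near-saturated factor order reproduces the sample covariance", {
  set.seed(62)
  S <- 5
  A <- matrix(rnorm(S * S), S)
  Sigma <- crossprod(A) + diag(0.3, S)
  X <- matrix(rnorm(600 * S), 600) %*% chol(Sigma)
  fa <- suppressWarnings(fit_fa(X, S - 1, max_iter = 5000, tol = 1e-10))
  ## the EM centres the data first, so its target is the divisor-n
  ## maximum-likelihood covariance
  n <- nrow(X)
  Sml <- stats::cov(X) * (n - 1) / n
  expect_lt(norm(fa$G - Sml, "F") / norm(Sml, "F"), 1e-3)
})

test_that("loadings obey the lower-triangular identification", {
  set.seed(63)
  X <- matrix(rnorm(400), 100, 4) %*% matrix(rnorm(16), 4) +
    matrix(rnorm(400, 0, 0.3), 100)
  fa <- suppressWarnings(fit_fa(X, 2, max_iter = 500))
  expect_lt(abs(fa$loadings[1, 2]), 1e-8)
  expect_gte(fa$loadings[1, 1], 0)
})

test_that("genetic correlations come out of the implied covariance", {
  mk_model <- function(L, psi) {
    L <- as.matrix(L)
    structure(list(loadings = L, psi = psi,
                   G = tcrossprod(L) + diag(psi, nrow(L)), k = ncol(L)),
              class = "fa_model")
  }
  ## identical rows, psi = 0: all correlations 1
  m1 <- mk_model(matrix(1, 3, 1), rep(0, 3))
  expect_equal(unname(genetic_correlation(m1)), matrix(1, 3, 3))
  ## orthogonal one-hot rows: off-diagonals 0
  m2 <- mk_model(diag(2), rep(0, 2))
  expect_equal(unname(genetic_correlation(m2)), diag(2))
  ## two sites with loading 1 and psi 1 each: correlation 1/2
  m3 <- mk_model(matrix(1, 2, 1), c(1, 1))
  expect_equal(genetic_correlation(m3)[1, 2], 0.5)
  ## zero-variance site: NA with warning
  m4 <- mk_model(matrix(c(1, 0), 2, 1), c(0.5, 0))
  expect_warning(C <- genetic_correlation(m4), "zero")
  expect_true(is.na(C[1, 2]))
})

test_that("variance explained behaves over the factor index", {
  mk_model <- function(L, psi) {
    L <- as.matrix(L)
    structure(list(loadings = L, psi = psi,
                   G = tcrossprod(L) + diag(psi, nrow(L)), k = ncol(L)),
              class = "fa_model")
  }
  m <- mk_model(matrix(1, 2, 1), c(1, 1))
  expect_equal(unname(variance_explained(m, 1)$per_site), c(50, 50))
  expect_equal(variance_explained(m, 1)$overall, 50)
  expect_equal(variance_explained(m, 0)$overall, 0)
  ## psi = 0, m = k: 100% everywhere
  m0 <- mk_model(cbind(c(1, 2, 0.5), c(0, 1, 1)), rep(0, 3))
  expect_equal(unname(variance_explained(m0, 2)$per_site), rep(100, 3))
  ## monotone in m
  mbig <- mk_model(cbind(c(1, 2, 0.5), c(0, 1, 1)), c(0.2, 0.1, 0.3))
  v <- vapply(0:2, function(mm) variance_explained(mbig, mm)$overall, 1)
  expect_true(all(diff(v) >= 0))
  expect_error(variance_explained(mbig, 3), "exceeds")
})

test_that("site clustering recovers planted blocks and flags degeneracy", {
  C <- site_cluster_corr(rep(1:2, each = 4), 0.8, -0.2)
  dimnames(C) <- list(paste0("S", 1:8), paste0("S", 1:8))
  cl <- cluster_sites(C)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])
  ## identity correlation: degenerate heights, 1 cluster with warning
  expect_warning(cl1 <- cluster_sites(diag(5)), "degenerate")
  expect_equal(cl1$n_clusters, 1)
  expect_error(cluster_sites(C, n_clusters = 9), "exceeds")
  ## permutation invariance of the partition
  p <- c(3, 7, 1, 5, 2, 8, 6, 4)
  clp <- cluster_sites(C[p, p])
  expect_equal(unname(clp$labels[order(p)] == clp$labels[order(p)][1]),
               unname(cl$labels == cl$labels[1]))
})

test_that("sparse site pairs are excluded with a warning", {
  set.seed(64)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  X[2:40, 3] <- NA  # site C shares only one genotype with the others
  expect_warning(fa <- fit_fa(X, 1), "shared genotypes")
  expect_equal(fa$sites, c("A", "B"))
})
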