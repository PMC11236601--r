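test_that("the GRM has VanRaden scaling properties on inbred panels", {
  fp <- simulate_founders(2, 20, 1000, 0.2, seed = 71)
  grm <- compute_grm(fp$dosage)
  ## inbred diagonal reflects f = 1 under method-1 scaling
  expect_lt(abs(mean(diag(grm$K)) - 2), 0.1)
  expect_true(isSymmetric(grm$K))
  ## duplicated individual: identical rows and K_ii = K_ij
  d2 <- rbind(fp$dosage, dup = fp$dosage[1, ])
  g2 <- compute_grm(d2)
  expect_equal(g2$K["dup", ], g2$K["P001", ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(g2$K["dup", "P001"], g2$K["dup", "dup"], tolerance = 1e-10)
})

test_that("unrelated panels have near-zero mean off-diagonal kinship", {
  ## observed-frequency centring induces a -diag/(n-1) finite-sample offset,
  ## so the panel must be large enough for the mean off-diagonal to sit
  ## within +/- 0.05 of zero
  fp <- simulate_founders(1, 80, 2000, 0.05, seed = 72)
  K <- compute_grm(fp$dosage)$K
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
})

test_that("the GRM is invariant to marker and individual order", {
  fp <- simulate_founders(2, 8, 200, 0.3, seed = 73)
  K <- compute_grm(fp$dosage)$K
  pm <- sample(ncol(fp$dosage)); pi <- sample(nrow(fp$dosage))
  K2 <- compute_grm(fp$dosage[pi, pm])$K
  expect_equal(K2[rownames(K), colnames(K)], K, tolerance = 1e-12)
  expect_error(compute_grm(matrix(2L, 4, 5)), "monomorphic")
})

test_that("GBLUP equals ridge regression on markers", {
  fp <- simulate_founders(2, 10, 100, 0.2, seed = 74)
  set.seed(74)
  n <- nrow(fp$dosage)
  grm <- compute_grm(fp$dosage)
  y <- drop(grm$Z %*% rnorm(100, 0, 0.05)) + rnorm(n, 0, 0.5)
  names(y) <- rownames(fp$dosage)
  s2a <- 0.4; s2e <- 0.3
  gb <- suppressWarnings(gblup_solve(y, grm, variances = c(s2a, s2e)))
  ## independent ridge route in marker space
  Z <- grm$Z
  lam <- s2e / (s2a / grm$scale)
  one <- rep(1, n)
  V <- (s2a / grm$scale) * tcrossprod(Z) + diag(s2e, n)
  Vi <- solve(V)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  alpha <- solve(crossprod(Z) + diag(lam, ncol(Z)), crossprod(Z, y - mu))
  expect_lt(max(abs(gb$gebv - drop(Z %*% alpha))), 1e-8)
})

test_that("zero additive variance shrinks every GEBV to zero", {
  fp <- simulate_founders(2, 8, 100, 0.2, seed = 75)
  grm <- compute_grm(fp$dosage)
  y <- stats::setNames(rnorm(16), rownames(fp$dosage))
  gb <- suppressWarnings(gblup_solve(y, grm, variances = c(1e-12, 1)))
  expect_lt(max(abs(gb$gebv)), 1e-6)
})

test_that("an unphenotyped parent borrows signal through kinship", {
  fp <- simulate_founders(1, 10, 300, 0.1, seed = 76)
  d <- rbind(fp$dosage, twin = fp$dosage[1, ])  # relative of P001, no data
  grm <- compute_grm(d)
  set.seed(76)
  y <- stats::setNames(2 + rnorm(10, 0, 0.1) + c(3, rep(0, 9)),
                       rownames(fp$dosage))
  design <- cbind(diag(10), 0)
  colnames(design) <- rownames(d)
  gb <- suppressWarnings(gblup_solve(y, grm, design = design,
                                     variances = c(1, 0.1)))
  expect_gt(abs(gb$gebv["twin"]), 0.5)
  expect_gt(gb$gebv["twin"] * gb$gebv["P001"], 0)  # same sign as its twin
})

test_that("marker backsolving reconstructs the GEBVs", {
  fp <- simulate_founders(2, 10, 300, 0.2, seed = 77)
  grm <- compute_grm(fp$dosage)
  set.seed(77)
  y <- stats::setNames(drop(grm$Z %*% rnorm(300, 0, 0.05)) + rnorm(20, 0, 0.3),
                       rownames(fp$dosage))
  gb <- suppressWarnings(gblup_solve(y, grm, variances = c(0.5, 0.3)))
  al <- suppressMessages(backsolve_markers(gb$gebv, grm))
  expect_lt(max(abs(drop(grm$Z %*% al$effect) - gb$gebv)), 1e-8)
  ## zero GEBVs give zero effects
  al0 <- suppressMessages(backsolve_markers(rep(0, 20), grm))
  expect_equal(al0$effect, rep(0, 300))
  ## backsolve of a reconstructed vector is a fixed point
  al2 <- suppressMessages(backsolve_markers(drop(grm$Z %*% al$effect), grm))
  expect_equal(al2$effect, al$effect, tolerance = 1e-8)
})

test_that("effect profiles flag the top fraction and measure concordance", {
  set.seed(78)
  eff <- stats::setNames(rnorm(100), sprintf("M%05d", 1:100))
  pr <- effect_profile(eff, top_fraction = 0.10)
  expect_equal(sum(pr$top), 10)
  expect_true(all(abs(pr$effect[pr$top]) >=
                    max(abs(pr$effect[!pr$top]))))
  ## ties broken by marker order
  tied <- stats::setNames(rep(1, 4), paste0("m", 1:4))
  prt <- effect_profile(tied, top_fraction = 0.5)
  expect_equal(prt$marker[prt$top], c("m1", "m2"))
  ## identical vectors: perfect concordance
  pr2 <- effect_profile(eff, other = eff)
  cc <- attr(pr2, "concordance")
  expect_equal(cc$correlation, 1)
  expect_equal(cc$sign_agreement, 1)
})
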