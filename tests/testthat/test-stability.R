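test_that("the stability estimator matches a brute-force oracle exactly", {
  X <- matrix(c(5, 7, 6,
                4, 4, 9,
                8, 3, 2,
                1, 6, 5), 4, 3, byrow = TRUE)
  rownames(X) <- paste0("g", 1:4)
  out <- shukla_variance(X)
  expect_equal(out$sigma2, shukla_brute(X), tolerance = 1e-12)
  expect_equal(out$mean, rowMeans(X), ignore_attr = TRUE)
  expect_equal(out$sigma2_trunc, pmax(out$sigma2, 0))
})

test_that("parallel response profiles have exactly zero stability variance", {
  base <- c(1, 4, 2, 6)
  X <- outer(c(0, 1, 3, 5, 2), rep(1, 4)) + outer(rep(1, 5), base)
  out <- shukla_variance(X)
  expect_equal(out$sigma2, rep(0, 5), tolerance = 1e-12)
})

test_that("a no-interaction genotype among interacting ones is the most stable", {
  set.seed(81)
  X <- matrix(rnorm(15, 0, 2), 5, 3)
  X[1, ] <- colMeans(X[2:5, ]) + 1  # parallel to the environment means
  ## recenter so genotype 1 has zero interaction residuals
  Xc <- X
  Xc[1, ] <- mean(X[1, ]) + (colMeans(X) - mean(colMeans(X)))
  out <- shukla_variance(Xc)
  expect_equal(which.min(out$sigma2), 1L)
  expect_lte(out$sigma2[1], 0 + 1e-12)
})

test_that("stability variances are location-invariant in environment effects", {
  set.seed(82)
  X <- matrix(rnorm(24), 6, 4)
  X2 <- X; X2[, 2] <- X2[, 2] + 5
  expect_equal(shukla_variance(X)$sigma2, shukla_variance(X2)$sigma2,
               tolerance = 1e-10)
})

test_that("stability variances reconstruct the interaction sum of squares", {
  set.seed(83)
  X <- matrix(rnorm(40), 8, 5)
  out <- shukla_variance(X)
  G <- 8; E <- 5
  W <- X - rowMeans(X)[row(X)] - colMeans(X)[col(X)] + mean(X)
  expect_equal(sum(out$sigma2) * (G - 1) * (E - 1) / G, sum(W^2),
               tolerance = 1e-10)
})

test_that("genotype permutation permutes the output rows identically", {
  set.seed(84)
  X <- matrix(rnorm(21), 7, 3, dimnames = list(paste0("g", 1:7), NULL))
  p <- sample(7)
  a <- shukla_variance(X)
  b <- shukla_variance(X[p, ])
  expect_equal(b$sigma2[match(a$genotype, b$genotype)], a$sigma2,
               tolerance = 1e-12)
})

test_that("degenerate tables are rejected and incomplete ones mean-filled", {
  expect_error(shukla_variance(matrix(1:4, 2, 2)), "3 genotypes")
  X <- matrix(rnorm(20), 5, 4)
  X[2, 3] <- NA
  expect_error(shukla_variance(X, complete = TRUE), "missing")
  expect_warning(out <- shukla_variance(X, complete = FALSE), "mean-filling")
  expect_equal(nrow(out), 5)
  expect_true(all(is.finite(out$sigma2)))
})

test_that("quadrant classification identifies stable positive parents", {
  tab <- data.frame(genotype = c("a", "b", "c", "d"),
                    mean = c(0.5, 0.5, -0.5, -0.1),
                    sqrt_stability = c(0, 2, 0.1, 1.5))
  out <- quadrant_classify(tab, stability_threshold = 1)
  expect_equal(as.character(out$quadrant),
               c("stable-positive", "unstable-positive",
                 "stable-negative", "unstable-negative"))
  ## a negative-mean parent is never stable-positive, whatever its variance
  out2 <- quadrant_classify(data.frame(genotype = "x", mean = -0.5,
                                       sqrt_stability = 0),
                            stability_threshold = 1)
  expect_false(out2$quadrant == "stable-positive")
  ## default threshold is the panel median
  out3 <- quadrant_classify(tab)
  expect_equal(attr(out3, "stability_threshold"),
               stats::median(tab$sqrt_stability))
})

test_that("a subgroup with stable positive GCA is enriched in its quadrant", {
  set.seed(85)
  reps <- sapply(1:10, function(r) {
    good <- matrix(rnorm(8 * 6, 0.8, 0.15), 8, 6)   # high mean, low GxE
    rest <- matrix(rnorm(24 * 6, 0, 1), 24, 6)      # centred, noisy
    X <- rbind(good, rest)
    rownames(X) <- paste0("p", 1:32)
    st <- shukla_variance(X)
    st <- quadrant_classify(st)
    grp <- rep(c("G1", "other"), c(8, 24))
    tab <- table(grp, st$quadrant == "stable-positive")
    if (ncol(tab) < 2) return(NA)
    stats::fisher.test(tab)$estimate < 1  # odds of G1 NOT stable-pos below 1
  })
  expect_gte(mean(reps, na.rm = TRUE), 0.9)
})
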