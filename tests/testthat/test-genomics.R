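test_that("marker QC excludes exactly the markers past either threshold", {
  n <- 20
  mk <- function(het_n, miss_n) {
    d <- rep(0L, n)
    if (het_n > 0) d[seq_len(het_n)] <- 1L
    if (miss_n > 0) d[n - seq_len(miss_n) + 1] <- NA
    d
  }
  ## het fractions {0, .2, .6} x missing {0, .05, .2}; het fraction is over
  ## non-missing calls
  combos <- expand.grid(het = c(0, 4, 12), miss = c(0, 1, 4))
  dosage <- do.call(cbind, lapply(seq_len(nrow(combos)), function(i)
    mk(combos$het[i], combos$miss[i])))
  colnames(dosage) <- sprintf("m%d", seq_len(ncol(dosage)))
  keep_expected <- vapply(seq_len(nrow(combos)), function(i) {
    het_frac <- combos$het[i] / (n - combos$miss[i])
    het_frac <= 0.5 && combos$miss[i] / n <= 0.1
  }, logical(1))
  out <- filter_markers(dosage)
  expect_identical(colnames(out), colnames(dosage)[keep_expected])

  ## a marker with 60% heterozygous calls is excluded
  m60 <- matrix(c(rep(1L, 12), rep(0L, 8)), ncol = 1,
                dimnames = list(NULL, "h60"))
  expect_equal(ncol(filter_markers(cbind(m60, clean = rep(2L, 20)))), 1)
  expect_error(filter_markers(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("complete-linkage pruning keeps one marker per r2=1 group", {
  set.seed(21)
  base <- matrix(sample(c(0L, 2L), 30 * 50, replace = TRUE), 30, 50)
  colnames(base) <- sprintf("m%02d", 1:50)
  dup_of <- sample(1:50, 5)
  dups <- base[, dup_of, drop = FALSE]
  colnames(dups) <- sprintf("dup%d", 1:5)
  x <- cbind(base, dups)
  ## complement column: r^2 = 1 with m01
  x <- cbind(x, comp = 2L - base[, 1])
  out <- suppressMessages(prune_complete_ld(x))
  ## brute-force oracle: greedy first-kept scan over all pairs
  v <- apply(x, 2, stats::var)
  poly <- which(v > 0)
  r <- abs(stats::cor(x[, poly]))
  keep <- rep(TRUE, length(poly))
  for (j in seq_along(poly)[-1])
    if (any(r[which(keep[seq_len(j - 1)]), j] >= 1 - 1e-12)) keep[j] <- FALSE
  expect_identical(colnames(out), colnames(x)[poly][keep])
  ## no surviving pair has r^2 = 1
  rr <- stats::cor(out)
  diag(rr) <- 0
  expect_lt(max(abs(rr)), 1 - 1e-12)
  ## duplicated column: exactly one survives
  two <- cbind(a = base[, 2], b = base[, 2])
  expect_equal(colnames(suppressMessages(prune_complete_ld(two))), "a")
})

test_that("QC then pruning is idempotent", {
  fp <- simulate_founders(2, 15, 200, 0.3, seed = 22)
  g1 <- suppressMessages(prune_complete_ld(filter_markers(fp$dosage)))
  g2 <- suppressMessages(prune_complete_ld(filter_markers(g1)))
  expect_identical(dim(g2), dim(g1))
  expect_identical(colnames(g2), colnames(g1))
  expect_equal(g2, g1, ignore_attr = TRUE)
  expect_length(attr(g2, "removed"), 0)
})

test_that("Rogers' distance matches its closed-form anchor cases", {
  a <- rep(2L, 10); b <- rep(0L, 10)
  d <- rogers_distance(rbind(i1 = a, i2 = a, i3 = b))
  expect_equal(d["i1", "i2"], 0)
  expect_equal(d["i1", "i3"], 1)   # opposite homozygotes everywhere
  ## opposite at exactly half the loci -> 0.5
  half <- c(rep(0L, 5), rep(2L, 5))
  d2 <- rogers_distance(rbind(x = a, y = half))
  expect_equal(d2["x", "y"], 0.5)
  expect_true(isSymmetric(d))
  ## zero shared loci is an error naming the pair
  m <- rbind(p = c(2L, NA), q = c(NA, 0L))
  expect_error(rogers_distance(m), "p.*q")
})

test_that("Rogers' distance is a metric on small panels", {
  fp <- simulate_founders(3, 4, 80, 0.25, seed = 23)
  d <- rogers_distance(fp$dosage)
  n <- nrow(d)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
    expect_lte(d[j, k], d[j, i] + d[i, k] + 1e-12)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  ## points on a line
  x <- c(0, 1, 2, 5, 9)
  d <- as.matrix(dist(x))
  pc <- pcoa_coords(d, 2)
  expect_equal(as.matrix(dist(pc$coords[, 1])), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## 3 equidistant individuals: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  pc3 <- pcoa_coords(d3, 2)
  pos <- pc3$eig[pc3$eig > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-8)
  ## full pairwise-distance reconstruction for a 2-D cloud
  set.seed(24)
  pts <- matrix(rnorm(20), 10, 2)
  pc2 <- pcoa_coords(as.matrix(dist(pts)), 2)
  expect_equal(as.matrix(dist(pc2$coords)), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)
})
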