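mk_map <- function(markers, chrom, cM) {
  m <- data.frame(marker = markers, chrom = chrom, cM = cM)
  class(m) <- c("genetic_map", "data.frame")
  m
}

test_that("selfing an inbred gives identical progeny with zero variance", {
  map <- mk_map(paste0("m", 1:6), 1, seq(0, 50, 10))
  p <- stats::setNames(c(2, 0, 2, 2, 0, 0), paste0("m", 1:6))
  pop <- simulate_dh(p, p, map, n = 30, seed = 91)
  expect_true(all(pop$dosage == matrix(p[colnames(pop$dosage)], 30, 6,
                                       byrow = TRUE)))
  vals <- gebv_score(pop, stats::setNames(rnorm(6), paste0("m", 1:6)))
  expect_equal(stats::sd(vals), 0)
})

test_that("DH progeny are fully homozygous and segregate at 1:1", {
  map <- mk_map(paste0("m", 1:10), rep(1:2, each = 5),
                rep(seq(0, 80, 20), 2))
  p1 <- stats::setNames(rep(2, 10), paste0("m", 1:10))
  p2 <- stats::setNames(rep(0, 10), paste0("m", 1:10))
  pop <- simulate_dh(p1, p2, map, n = 250, seed = 92)
  expect_true(all(pop$dosage %in% c(0L, 2L)))
  freq <- colMeans(pop$dosage) / 2
  se3 <- 3 * sqrt(0.25 / 250)
  expect_true(all(abs(freq - 0.5) < se3 + 0.02))
  ## aggregate binomial goodness of fit across loci
  chi <- sum((colSums(pop$dosage == 2) - 125)^2 / (250 * 0.25))
  expect_lt(chi, stats::qchisq(0.999, df = 10))
})

test_that("recombination matches Haldane's map function and saturates at 0.5", {
  dists <- c(5, 10, 40, 200)
  rf <- vapply(seq_along(dists), function(i) {
    map <- mk_map(c("a", "b"), 1, c(0, dists[i]))
    p1 <- c(a = 2, b = 2); p2 <- c(a = 0, b = 0)
    pop <- simulate_dh(p1, p2, map, n = 10000, seed = 93 + i)
    mean(pop$dosage[, "a"] != pop$dosage[, "b"])
  }, numeric(1))
  haldane <- (1 - exp(-2 * dists / 100)) / 2
  expect_true(all(abs(rf - haldane) < 0.015))
  expect_true(all(diff(rf) > -0.02))   # monotone in map distance (MC tolerance)
  expect_true(all(rf <= 0.52))
})

test_that("inbred-parent and map preconditions are enforced", {
  map <- mk_map(c("a", "b"), 1, c(0, 10))
  expect_error(simulate_dh(c(a = 1, b = 2), c(a = 0, b = 0), map),
               "inbred")
  ## unmapped markers are dropped with a message
  p1 <- c(a = 2, b = 2, z = 2); p2 <- c(a = 0, b = 0, z = 0)
  expect_message(pop <- simulate_dh(p1, p2, map, n = 5, seed = 94),
                 "unmapped")
  expect_equal(colnames(pop$dosage), c("a", "b"))
})

test_that("progeny GEBVs are the dosage-effect inner product plus the site mean", {
  map <- mk_map(paste0("m", 1:3), 1, c(0, 10, 20))
  ## zero effects: every value equals the site mean
  p1 <- stats::setNames(c(2, 2, 0), paste0("m", 1:3))
  p2 <- stats::setNames(c(0, 2, 0), paste0("m", 1:3))
  pop <- simulate_dh(p1, p2, map, n = 40, seed = 95)
  expect_equal(gebv_score(pop, stats::setNames(rep(0, 3), paste0("m", 1:3)),
                          site_mean = 6), rep(6, 40), ignore_attr = TRUE)
  ## single segregating marker with effect 0.1: two-point support
  e1 <- stats::setNames(c(0.1, 0, 0), paste0("m", 1:3))
  vals <- gebv_score(pop, e1, site_mean = 6)
  expect_true(all(vals %in% c(6, 6.2)))
  ## hand-computed dot product on a fixed 2 x 3 dosage matrix
  dm <- matrix(c(2, 0, 2,
                 0, 2, 2), 2, 3, byrow = TRUE,
               dimnames = list(NULL, paste0("m", 1:3)))
  ee <- stats::setNames(c(0.5, -0.25, 0.1), paste0("m", 1:3))
  expect_equal(gebv_score(dm, ee, 1), c(1 + 1.2, 1 + (-0.5 + 0.2)))
  expect_error(gebv_score(pop, stats::setNames(1, "mX")), "no effect")
})

test_that("selection intensity follows the normal tail formula", {
  expect_equal(selection_intensity(0.5), sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(selection_intensity(0.10), 1.7550, tolerance = 1e-3)
  expect_lt(selection_intensity(0.999), 0.01)
  expect_error(selection_intensity(0))
  expect_error(selection_intensity(1))
  ## Monte-Carlo truncated-normal cross-check
  set.seed(96)
  z <- rnorm(4e5)
  expect_equal(mean(z[z > stats::qnorm(0.9)]), selection_intensity(0.10),
               tolerance = 5e-3)
})

test_that("the usefulness criterion composes mean, intensity and spread", {
  v <- c(5.5, 6.0, 6.5)
  uc <- usefulness_criterion(v, p = 0.10, h = 1)
  expect_equal(uc$uc, mean(v) + selection_intensity(0.10) * stats::sd(v))
  ## sigma = 0 and h = 0 both collapse UC to the mean
  expect_equal(usefulness_criterion(rep(3, 5))$uc, 3)
  expect_equal(usefulness_criterion(v, h = 0)$uc, mean(v))
  ## strictly increasing in sigma at fixed mean
  uc1 <- usefulness_criterion(c(5.9, 6.1))$uc
  uc2 <- usefulness_criterion(c(5.5, 6.5))$uc
  expect_gt(uc2, uc1)
  expect_error(usefulness_criterion(1), "two progeny")
})

test_that("cross-set comparison is well-bookkept and seed-stable", {
  cp <- simulate_complementary_panel(n_per_group = 4, n_markers = 60, seed = 97)
  map <- simulate_map(3, 20, 100, marker_ids = colnames(cp$panel$dosage),
                      seed = 97)
  ## zero effects: all UC equal the site mean, no category contrast
  zero <- stats::setNames(rep(0, 60), colnames(cp$panel$dosage))
  res0 <- compare_cross_sets(cp$panel, 1, zero, map, site_means = 6, n = 20,
                             seed = 97)
  expect_equal(res0$uc, rep(6, nrow(res0)))
  ## bookkeeping: 4 anchors -> C(4,2)=6 intra + 4*4=16 inter crosses
  expect_equal(sum(res0$category == "intra"), 6)
  expect_equal(sum(res0$category == "inter"), 16)
  ## reproducibility
  res1 <- compare_cross_sets(cp$panel, 1, cp$effects, map, n = 20, seed = 98)
  res2 <- compare_cross_sets(cp$panel, 1, cp$effects, map, n = 20, seed = 98)
  expect_identical(res1, res2)
  expect_error(compare_cross_sets(cp$panel, 9, cp$effects, map), "absent")
})
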