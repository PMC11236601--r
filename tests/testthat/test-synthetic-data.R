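test_that("founder panels are fully inbred with valid subgroup labels", {
  fp <- simulate_founders(K = 4, n_per_group = 8, n_markers = 150,
                          fst = 0.2, seed = 3)
  expect_true(all(fp$dosage %in% c(0L, 2L)))
  expect_setequal(unique(fp$membership), 1:4)
  expect_equal(dim(fp$dosage), c(32, 150))
  expect_error(simulate_founders(0, 5, 10, 0.2, 1))
  expect_error(simulate_founders(2, 5, 10, 1.2, 1), "fst")
  expect_error(simulate_founders(2, 5, 10, 0, 1), "fst")
})

test_that("single-population panels show no structure; diverged panels separate", {
  ## K = 1, near-zero divergence: pairwise distances concentrate
  fp1 <- simulate_founders(1, 24, 400, 1e-6, seed = 5)
  d1 <- rogers_distance(fp1$dosage)
  off <- d1[upper.tri(d1)]
  expect_lt(stats::sd(off) / mean(off), 0.15)

  ## K = 3, fst = 0.15: true groups separate on the first two PCo axes
  fp3 <- simulate_founders(3, 20, 500, 0.15, seed = 5)
  pc <- pcoa_coords(rogers_distance(fp3$dosage), 2)
  expect_gt(silhouette_mean(pc$coords, fp3$membership), 0)
})

test_that("genetic maps have the requested size and bounded sorted positions", {
  map <- simulate_map(21, 10, 150, seed = 2)
  expect_equal(nrow(map), 210)
  expect_equal(length(unique(map$chrom)), 21)
  expect_true(all(map$cM >= 0 & map$cM <= 150))
  expect_true(all(tapply(map$cM, map$chrom, function(x) !is.unsorted(x))))
  ## degenerate single-marker chromosomes are still a valid map
  m1 <- simulate_map(3, 1, 100, seed = 2)
  expect_equal(nrow(m1), 3)
})

test_that("yields collapse to the site mean when every variance is zero", {
  x <- make_tiny_met(seed = 7, sigma2_a = 0, sigma2_s = 0, sigma2_e = 0,
                     sigma2_row = 0, sigma2_col = 0, sigma2_block = 0,
                     site_mean = 5.5)
  hy <- x$met$pheno[!x$met$pheno$is_check, ]
  expect_equal(hy$yield, rep(5.5, nrow(hy)), tolerance = 1e-12)
})

test_that("p-rep duplicate plots are equal in the noise-free limit", {
  x <- make_tiny_met(seed = 8, sigma2_a = 0.5, sigma2_s = 0, sigma2_e = 0,
                     sigma2_row = 0, sigma2_col = 0, sigma2_block = 0)
  ph <- x$met$pheno[x$met$pheno$site == "S01" & !x$met$pheno$is_check, ]
  dup <- ph$entry[duplicated(ph$entry)]
  expect_gt(length(dup), 0)
  for (e in dup) {
    yv <- ph$yield[ph$entry == e]
    expect_equal(max(yv) - min(yv), 0, tolerance = 1e-10)
  }
})

test_that("perfect between-site additive correlation gives identical GCA vectors", {
  x <- make_tiny_met(seed = 9, sites = 2, hybrids_per_site = 30,
                     site_corr = matrix(c(1, 1, 1, 1), 2))
  expect_equal(x$met$true_gca[, 1], x$met$true_gca[, 2], tolerance = 1e-4)
})

test_that("hybrid additive variance approaches twice the GCA variance", {
  fp <- simulate_founders(1, 150, 50, 0.1, seed = 10)
  ids <- rownames(fp$dosage)
  plan <- make_cross_plan(ids[1:100], ids[101:150], 2000, 1, 100, seed = 10)
  tr <- truth_params(1, sigma2_a = 0.8, sigma2_s = 0, sigma2_e = 0,
                     sigma2_row = 0, sigma2_col = 0, sigma2_block = 0)
  met <- simulate_met(fp, plan, tr, seed = 10)
  gca <- met$true_gca[, 1]
  add <- gca[plan$crosses$male] + gca[plan$crosses$female]
  ## the invariant: hybrid additive variance -> 2 x GCA variance
  expect_equal(stats::var(add) / (2 * stats::var(gca)), 1, tolerance = 0.1)
})

test_that("the generator is bit-for-bit reproducible under a fixed seed", {
  a <- make_tiny_met(seed = 11)
  b <- make_tiny_met(seed = 11)
  expect_identical(a$met$pheno, b$met$pheno)
  c <- make_tiny_met(seed = 12)
  expect_false(identical(a$met$pheno$yield, c$met$pheno$yield))
})

test_that("invalid correlation structures are rejected", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(truth_params(3, site_corr = bad), "semi-definite")
  expect_error(truth_params(2, site_corr = matrix(c(2, 0, 0, 2), 2)), "diagonal")
})
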