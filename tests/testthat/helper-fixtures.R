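# Shared in-code fixtures: all data is generated, nothing is read from disk.

# tiny panel + plan + truth, used by several module tests
make_tiny_met <- function(seed = 1, sites = 4, n_hybrids = 60,
                          hybrids_per_site = 40, sigma2_a = 0.5,
                          sigma2_s = 0.1, sigma2_e = 1.0,
                          site_corr = diag(sites), ...) {
  fp <- simulate_founders(2, 10, 120, 0.2, seed = seed)
  ids <- rownames(fp$dosage)
  plan <- make_cross_plan(ids[1:14], ids[15:20], n_hybrids, sites,
                          hybrids_per_site, seed = seed)
  tr <- truth_params(sites, sigma2_a = sigma2_a, sigma2_s = sigma2_s,
                     sigma2_e = sigma2_e, site_corr = site_corr, ...)
  met <- simulate_met(fp, plan, tr, seed = seed)
  list(panel = fp, plan = plan, truth = tr, met = met)
}

# independent brute-force evaluation of the stability-variance formula,
# written against the definition, not the package code
shukla_brute <- function(X) {
  G <- nrow(X); E <- ncol(X)
  w <- matrix(0, G, E)
  for (i in 1:G) for (j in 1:E)
    w[i, j] <- X[i, j] - mean(X[i, ]) - mean(X[, j]) + mean(X)
  ss_all <- sum(w^2)
  sapply(1:G, function(i)
    G * sum(w[i, ]^2) / ((G - 2) * (E - 1)) -
      ss_all / ((G - 1) * (G - 2) * (E - 1)))
}

indicator_test <- function(f) {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# silhouette of a labelling on a coordinate matrix (small-n, brute force)
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
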