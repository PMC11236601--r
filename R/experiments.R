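## Parameter-recovery experiments over the synthetic generator. These power
## the calibration checks in the test suite, the acceptance script and the
## analysis drivers, so the same experiment definition is run everywhere.

#' Desk-scale variance-recovery and cluster-recovery experiment
#'
#' For each seed, simulates the desk preset (8 sites in two environment
#' clusters, 200 hybrids of 40 parents, additive variance 0.5, SCA 0.1,
#' residual 1.0), fits the additive/non-additive single-trial model at
#' every site, and records (a) the mean estimated hybrid additive variance
#' (twice the parental GCA component) across sites and (b) whether the
#' factor-analytic stage followed by hierarchical clustering of the
#' additive genetic correlation recovers the two true environment clusters
#' exactly (cluster count fixed at the known value; the partition is the
#' quantity under test).
#'
#' @param n_seeds number of replicate simulations.
#' @param seed master seed.
#' @param config generator configuration (default \code{\link{desk_config}}).
#' @return data.frame per seed: \code{sigma2_a_hat} (site-mean estimate),
#'   \code{cluster_ok} (logical exact recovery).
#' @export
desk_recovery_experiment <- function(n_seeds = 20, seed = 1,
                                     config = desk_config()) {
  truecl <- config$site_cluster
  out <- lapply(seq_len(n_seeds), function(r) {
    s <- derive_seed(seed, paste0("desk", r))
    fp <- simulate_founders(config$K, config$n_per_group, config$n_markers,
                            config$fst, seed = s)
    ids <- rownames(fp$dosage)
    plan <- make_cross_plan(ids[seq_len(config$n_males)],
                            ids[(config$n_males + 1):length(ids)],
                            config$n_hybrids, config$sites,
                            config$hybrids_per_site, config$checks, seed = s)
    tr <- truth_params(config$sites, sigma2_a = config$sigma2_a,
                       sigma2_s = config$sigma2_s, sigma2_e = config$sigma2_e,
                       site_corr = site_cluster_corr(truecl, config$corr_within,
                                                     config$corr_between),
                       site_mean = config$site_mean)
    met <- simulate_met(fp, plan, tr, seed = s, prep_frac = config$prep_frac)
    sites <- unique(met$pheno$site)
    fits <- lapply(sites, function(ss)
      suppressWarnings(fit_trial(met$pheno[met$pheno$site == ss, ],
                                 genetic = "additive")))
    s2a <- mean(vapply(fits, function(f) 2 * unname(f$sigma2["additive"]),
                       numeric(1)))
    b <- do.call(rbind, Map(function(f, ss) {
      e <- f$effects[f$effects$observed_at_site, ]
      data.frame(site = ss, level = e$level, blup = e$blup)
    }, fits, sites))
    parents <- sort(unique(b$level))
    eff <- matrix(NA_real_, length(parents), length(sites),
                  dimnames = list(parents, sites))
    eff[cbind(match(b$level, parents), match(b$site, sites))] <- b$blup
    fa <- suppressWarnings(fit_fa(eff, k = 2, max_iter = 1000, tol = 1e-7))
    cl <- suppressWarnings(cluster_sites(genetic_correlation(fa),
                                         n_clusters = length(unique(truecl))))
    ok <- all(vapply(unique(truecl), function(g)
      length(unique(cl$labels[truecl == g])) == 1, logical(1))) &&
      length(unique(cl$labels[!duplicated(truecl)])) == length(unique(truecl))
    data.frame(seed = r, sigma2_a_hat = s2a, cluster_ok = ok)
  })
  do.call(rbind, out)
}

#' Cross-validated K selection experiment
#'
#' Simulates Balding-Nichols panels with 3 true subgroups (20 inbreds each,
#' 500 SNPs, Fst 0.15), applies the QC and pruning used before structure
#' analysis, and selects the number of ancestral populations by 3-fold
#' masked-entry cross-validation over candidates 2..6.
#'
#' @param n_reps number of seeded repetitions.
#' @param seed master seed.
#' @param k_max largest candidate K.
#' @return integer vector of selected K values, one per repetition.
#' @export
kselect_experiment <- function(n_reps = 10, seed = 1, k_max = 6) {
  vapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, paste0("ksel", r))
    fp <- simulate_founders(3, 20, 500, 0.15, seed = s)
    g <- suppressMessages(prune_complete_ld(filter_markers(fp$dosage)))
    select_K_cv(g, k_min = 2, k_max = k_max, folds = 3, seed = s)$K
  }, integer(1))
}

#' Usefulness-criterion contrast experiment under allele complementarity
#'
#' For each seed, builds a two-subgroup panel whose groups carry the
#' favourable allele at disjoint halves of the effect loci (so
#' inter-population crosses segregate everywhere while intra-population
#' crosses are nearly fixed), simulates DH progeny of every anchor cross
#' and compares the median usefulness criterion of inter- versus
#' intra-population crosses.
#'
#' @param n_seeds number of replicate simulations.
#' @param seed master seed.
#' @param n_dh DH progeny per cross.
#' @param n_per_group parents per subgroup.
#' @return data.frame per seed: median UC by category and the logical
#'   \code{inter_gt_intra}.
#' @export
uc_contrast_experiment <- function(n_seeds = 20, seed = 1, n_dh = 250,
                                   n_per_group = 5) {
  out <- lapply(seq_len(n_seeds), function(r) {
    s <- derive_seed(seed, paste0("uc", r))
    cp <- simulate_complementary_panel(n_per_group = n_per_group,
                                       n_markers = 100, seed = s)
    map <- simulate_map(5, 20, 150, marker_ids = colnames(cp$panel$dosage),
                        seed = s)
    res <- compare_cross_sets(cp$panel, 1, cp$effects, map, site_means = 6,
                              n = n_dh, seed = s)
    med <- tapply(res$uc, res$category, stats::median)
    data.frame(seed = r, median_inter = med[["inter"]],
               median_intra = med[["intra"]],
               inter_gt_intra = med[["inter"]] > med[["intra"]])
  })
  do.call(rbind, out)
}
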