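#' Ground-truth parameters for a simulated multi-environment trial
#'
#' Collects the variance components, spatial parameters and between-site
#' additive correlation structure used by \code{\link{simulate_met}}. The
#' additive variance \code{sigma2_a} is the per-site variance of hybrid
#' additive effects; parental general-combining-ability (GCA) vectors are
#' drawn with per-parent variance \code{sigma2_a / 2} so that the sum of two
#' independent parental GCAs has variance \code{sigma2_a}.
#'
#' @param sites number of trial sites.
#' @param sigma2_a per-site additive (hybrid) variance.
#' @param sigma2_s specific-combining-ability (non-additive) variance.
#' @param sigma2_e iid residual plot variance.
#' @param sigma2_row,sigma2_col,sigma2_block design-factor variances.
#' @param sigma2_spatial variance of the AR1 x AR1 correlated spatial field.
#' @param rho_r,rho_c spatial autocorrelation along rows and columns.
#' @param site_corr sites x sites additive genetic correlation matrix
#'   (symmetric PSD, unit diagonal).
#' @param site_mean per-site mean yield (t/ha); recycled to \code{sites}.
#' @param marker_effects optional markers x sites matrix of true additive
#'   marker effects; when supplied, parental GCAs are computed as centred
#'   dosage times these effects instead of being drawn from the Gaussian
#'   GCA model.
#' @return a \code{truth_params} list.
#' @export
truth_params <- function(sites, sigma2_a = 0.5, sigma2_s = 0.1, sigma2_e = 1.0,
                         sigma2_row = 0.05, sigma2_col = 0.05,
                         sigma2_block = 0.05, sigma2_spatial = 0,
                         rho_r = 0, rho_c = 0,
                         site_corr = diag(sites), site_mean = 6,
                         marker_effects = NULL) {
  sites <- check_count(sites, "sites")
  for (nm in c("sigma2_a", "sigma2_s", "sigma2_e", "sigma2_row", "sigma2_col",
               "sigma2_block", "sigma2_spatial"))
    check_scalar_number(get(nm), nm, lower = 0)
  check_scalar_number(rho_r, "rho_r", -1, 1, TRUE, TRUE)
  check_scalar_number(rho_c, "rho_c", -1, 1, TRUE, TRUE)
  site_corr <- as.matrix(site_corr)
  stop_if(nrow(site_corr) != sites || ncol(site_corr) != sites,
          "'site_corr' must be %d x %d", sites, sites)
  stop_if(max(abs(diag(site_corr) - 1)) > 1e-8, "'site_corr' must have unit diagonal")
  stop_if(!is_psd(site_corr), "'site_corr' must be symmetric positive semi-definite")
  if (!is.null(marker_effects)) marker_effects <- as.matrix(marker_effects)
  structure(list(sites = sites, sigma2_a = sigma2_a, sigma2_s = sigma2_s,
                 sigma2_e = sigma2_e, sigma2_row = sigma2_row,
                 sigma2_col = sigma2_col, sigma2_block = sigma2_block,
                 sigma2_spatial = sigma2_spatial, rho_r = rho_r, rho_c = rho_c,
                 site_corr = site_corr,
                 site_mean = rep_len(site_mean, sites),
                 marker_effects = marker_effects),
            class = "truth_params")
}

#' Block additive correlation matrix for clustered trial sites
#'
#' @param cluster integer/character cluster label per site.
#' @param within,between correlation within and between clusters.
#' @return sites x sites correlation matrix (validated PSD).
#' @export
site_cluster_corr <- function(cluster, within = 0.8, between = -0.2) {
  s <- length(cluster)
  m <- matrix(between, s, s)
  same <- outer(cluster, cluster, "==")
  m[same] <- within
  diag(m) <- 1
  stop_if(!is_psd(m), "cluster correlation (within=%g, between=%g) is not PSD",
          within, between)
  m
}

## AR1 correlation matrix over integer coordinates
ar1_corr <- function(coord, rho) rho ^ abs(outer(coord, coord, "-"))

#' Simulate plot-level yields for a sparse p-rep multi-environment trial
#'
#' Each site receives its allocated hybrid subset plus all checks; a fraction
#' of the site's hybrids is duplicated (partial replication) and plots are
#' arranged on a row x column grid with contiguous column blocks. Yield is
#' built as site mean + row/column/block effects + additive effect (male GCA
#' + female GCA, GCA vectors drawn jointly across sites under the truth's
#' between-site correlation, or from true marker effects when supplied) +
#' SCA + AR1 x AR1 spatial field + iid residual. All components scale by the
#' square root of their truth variance, so zero variances contribute exactly
#' zero.
#'
#' @param panel a \code{founder_panel} covering all parents in the plan.
#' @param plan a \code{cross_plan}.
#' @param truth a \code{truth_params} with \code{sites} equal to the plan's.
#' @param seed integer seed; same seed reproduces the table bit-for-bit.
#' @param prep_frac fraction of each site's hybrids grown in two plots.
#' @param check_reps plots per check per site.
#' @return list with \code{pheno} (stacked plot table: site, row, col, block,
#'   entry, male, female, is_check, yield), \code{true_gca} (parents x sites),
#'   \code{true_sca} (hybrids x sites) and the inputs' ids.
#' @export
simulate_met <- function(panel, plan, truth, seed = 1, prep_frac = 0.3,
                         check_reps = 2) {
  stopifnot(inherits(panel, "founder_panel"), inherits(plan, "cross_plan"),
            inherits(truth, "truth_params"))
  sites <- length(plan$site_alloc)
  stop_if(truth$sites != sites, "truth has %d sites, plan has %d", truth$sites, sites)
  parents <- rownames(panel$dosage)
  miss <- setdiff(unique(c(plan$crosses$male, plan$crosses$female)), parents)
  stop_if(length(miss) > 0, "parents not genotyped in panel: %s",
          paste(miss, collapse = ", "))
  set.seed(derive_seed(seed, "met"))

  np <- length(parents)
  ## parental GCA vectors across sites
  if (is.null(truth$marker_effects)) {
    L <- chol(truth$site_corr + diag(1e-10, sites))
    true_gca <- sqrt(truth$sigma2_a / 2) *
      (matrix(stats::rnorm(np * sites), np, sites) %*% L)
  } else {
    stop_if(nrow(truth$marker_effects) != ncol(panel$dosage),
            "marker_effects rows must equal panel marker count")
    Z <- scale(panel$dosage, center = TRUE, scale = FALSE)
    true_gca <- Z %*% truth$marker_effects
  }
  dimnames(true_gca) <- list(parents, names(plan$site_alloc))

  nh <- nrow(plan$crosses)
  true_sca <- sqrt(truth$sigma2_s) * matrix(stats::rnorm(nh * sites), nh, sites)
  dimnames(true_sca) <- list(plan$crosses$hybrid, names(plan$site_alloc))

  pheno <- vector("list", sites)
  for (s in seq_len(sites)) {
    hy <- plan$site_alloc[[s]]
    n_rep <- round(prep_frac * length(hy))
    rep_hy <- if (n_rep > 0) sample(hy, n_rep) else character(0)
    entries <- c(hy, rep_hy, rep(plan$checks, each = check_reps))
    n_plot <- length(entries)
    nrow_g <- ceiling(sqrt(n_plot))
    ncol_g <- ceiling(n_plot / nrow_g)
    cells <- sample.int(nrow_g * ncol_g, n_plot)
    row <- ((cells - 1L) %% nrow_g) + 1L
    col <- ((cells - 1L) %/% nrow_g) + 1L
    block <- 1L + as.integer(col > ncol_g / 2)
    ord <- sample.int(n_plot)  # entries to plots at random
    entries <- entries[ord]
    is_check <- entries %in% plan$checks

    re <- sqrt(truth$sigma2_row) * stats::rnorm(nrow_g)
    ce <- sqrt(truth$sigma2_col) * stats::rnorm(ncol_g)
    be <- sqrt(truth$sigma2_block) * stats::rnorm(max(block))
    ## AR1 x AR1 spatial field on the full grid
    if (truth$sigma2_spatial > 0) {
      Lr <- chol(ar1_corr(seq_len(nrow_g), truth$rho_r) + diag(1e-10, nrow_g))
      Lc <- chol(ar1_corr(seq_len(ncol_g), truth$rho_c) + diag(1e-10, ncol_g))
      field <- sqrt(truth$sigma2_spatial) *
        (t(Lr) %*% matrix(stats::rnorm(nrow_g * ncol_g), nrow_g) %*% Lc)
      sp <- field[cbind(row, col)]
    } else sp <- numeric(n_plot)

    idx <- match(entries, plan$crosses$hybrid)
    add <- ifelse(is_check, 0,
                  true_gca[match(plan$crosses$male[idx], parents), s] +
                    true_gca[match(plan$crosses$female[idx], parents), s])
    sca <- ifelse(is_check, 0, true_sca[idx, s])
    ## checks carry fixed offsets so they separate from the hybrid intercept
    chk_off <- ifelse(is_check, 0.3 * match(entries, plan$checks), 0)
    chk_off[is.na(chk_off)] <- 0
    yield <- truth$site_mean[s] + re[row] + ce[col] + be[block] + chk_off +
      add + sca + sp + sqrt(truth$sigma2_e) * stats::rnorm(n_plot)

    pheno[[s]] <- data.frame(site = names(plan$site_alloc)[s],
                             row = row, col = col, block = block,
                             entry = entries,
                             male = ifelse(is_check, NA, plan$crosses$male[idx]),
                             female = ifelse(is_check, NA, plan$crosses$female[idx]),
                             is_check = is_check, yield = yield,
                             stringsAsFactors = FALSE)
  }
  list(pheno = do.call(rbind, pheno), true_gca = true_gca, true_sca = true_sca,
       sites = names(plan$site_alloc))
}
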