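#' Simulate a structured panel of fully inbred founder lines
#'
#' Draws a panel of inbred lines from \code{K} genetic subgroups under the
#' Balding-Nichols model: each marker has an ancestral allele frequency
#' \eqn{p \sim U(0.05, 0.95)}, each subgroup draws its own frequency from
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} with divergence parameter \eqn{F}
#' (an Fst analogue), and each inbred line draws a single allele per marker,
#' recorded as dosage 0 or 2. This emulates a hybrid-breeding parent panel
#' composed of several distinct germplasm subgroups.
#'
#' @param K number of subgroups.
#' @param n_per_group inbred lines per subgroup (scalar or length-K vector).
#' @param n_markers number of biallelic markers.
#' @param fst divergence parameter in (0, 1).
#' @param seed integer seed.
#' @return A \code{founder_panel}: list with \code{dosage} (individuals x
#'   markers, entries 0/2), \code{membership} (integer subgroup per line),
#'   \code{K}, \code{fst}, \code{ancestral_freq} and \code{group_freq}.
#' @examples
#' fp <- simulate_founders(K = 3, n_per_group = 10, n_markers = 100,
#'                         fst = 0.2, seed = 1)
#' table(fp$membership)
#' @export
simulate_founders <- function(K, n_per_group, n_markers, fst, seed) {
  K <- check_count(K, "K")
  n_markers <- check_count(n_markers, "n_markers")
  check_scalar_number(fst, "fst", 0, 1, open_lower = TRUE, open_upper = TRUE)
  stop_if(any(n_per_group < 1), "'n_per_group' must be positive")
  n_per_group <- rep_len(as.integer(n_per_group), K)

  set.seed(derive_seed(seed, "founders"))
  p_anc <- stats::runif(n_markers, 0.05, 0.95)
  scale <- (1 - fst) / fst
  ## K x markers subgroup allele frequencies
  pg <- matrix(stats::rbeta(K * n_markers,
                            rep(p_anc, each = K) * scale,
                            rep(1 - p_anc, each = K) * scale),
               nrow = K)
  n_total <- sum(n_per_group)
  membership <- rep(seq_len(K), times = n_per_group)
  ## one allele draw per line per marker -> dosage 0/2
  u <- matrix(stats::runif(n_total * n_markers), nrow = n_total)
  dosage <- 2L * (u < pg[membership, , drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- sprintf("P%03d", seq_len(n_total))
  colnames(dosage) <- sprintf("M%05d", seq_len(n_markers))

  structure(list(dosage = dosage,
                 membership = stats::setNames(membership, rownames(dosage)),
                 K = K, fst = fst,
                 ancestral_freq = p_anc, group_freq = pg),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d inbred lines, %d markers, %d subgroups (fst = %g)\n",
              nrow(x$dosage), ncol(x$dosage), x$K, x$fst))
  invisible(x)
}

#' Simulate a genetic map
#'
#' Places markers uniformly at random along each chromosome (positions in
#' centimorgans), then sorts within chromosome.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_cM chromosome length in centimorgans.
#' @param marker_ids optional character vector of marker ids
#'   (length \code{n_chrom * markers_per_chrom}).
#' @param seed integer seed.
#' @return a \code{genetic_map} data.frame with columns \code{marker},
#'   \code{chrom}, \code{cM}, sorted by chromosome then position.
#' @export
simulate_map <- function(n_chrom, markers_per_chrom, chrom_length_cM = 150,
                         marker_ids = NULL, seed = 1) {
  n_chrom <- check_count(n_chrom, "n_chrom")
  markers_per_chrom <- check_count(markers_per_chrom, "markers_per_chrom")
  check_scalar_number(chrom_length_cM, "chrom_length_cM", 0, open_lower = TRUE)
  set.seed(derive_seed(seed, "map"))
  n <- n_chrom * markers_per_chrom
  if (is.null(marker_ids)) marker_ids <- sprintf("M%05d", seq_len(n))
  stop_if(length(marker_ids) != n, "need %d marker ids, got %d", n, length(marker_ids))
  chrom <- rep(seq_len(n_chrom), each = markers_per_chrom)
  pos <- stats::runif(n, 0, chrom_length_cM)
  ord <- order(chrom, pos)
  ## marker ids keep their original (genome) order; positions are sorted within chrom
  map <- data.frame(marker = marker_ids,
                    chrom = chrom,
                    cM = pos[ord],
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Build a sparse testcross plan
#'
#' Crosses male parents onto female parents to produce F1 test hybrids, then
#' allocates a random subset of hybrids to each trial site (sparse MET
#' allocation) and attaches a common set of check entries present at every
#' site.
#'
#' @param males,females character ids of male and female parents.
#' @param n_hybrids number of distinct male x female hybrids to create.
#' @param sites number of trial sites.
#' @param hybrids_per_site hybrids allocated to each site.
#' @param checks character ids of check cultivars (present at every site).
#' @param seed integer seed.
#' @return a \code{cross_plan}: list with \code{crosses} (data.frame hybrid,
#'   male, female), \code{site_alloc} (list of hybrid ids per site) and
#'   \code{checks}.
#' @export
make_cross_plan <- function(males, females, n_hybrids, sites,
                            hybrids_per_site, checks = paste0("CHK", 1:3),
                            seed = 1) {
  stop_if(length(males) < 1 || length(females) < 1, "need male and female parents")
  n_hybrids <- check_count(n_hybrids, "n_hybrids")
  sites <- check_count(sites, "sites")
  hybrids_per_site <- check_count(hybrids_per_site, "hybrids_per_site")
  stop_if(hybrids_per_site > n_hybrids, "'hybrids_per_site' exceeds 'n_hybrids'")
  all_pairs <- expand.grid(male = males, female = females,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stop_if(n_hybrids > nrow(all_pairs), "more hybrids requested than distinct pairs")
  set.seed(derive_seed(seed, "crossplan"))
  sel <- all_pairs[sample.int(nrow(all_pairs), n_hybrids), , drop = FALSE]
  crosses <- data.frame(hybrid = sprintf("H%04d", seq_len(n_hybrids)),
                        male = sel$male, female = sel$female,
                        stringsAsFactors = FALSE)
  site_alloc <- lapply(seq_len(sites), function(s)
    sort(sample(crosses$hybrid, hybrids_per_site)))
  names(site_alloc) <- sprintf("S%02d", seq_len(sites))
  structure(list(crosses = crosses, site_alloc = site_alloc, checks = checks),
            class = "cross_plan")
}

#' Construct a two-subgroup panel with complementary favourable alleles
#'
#' Builds ground truth for usefulness-criterion contrasts: two inbred
#' subgroups carry the favourable allele at disjoint marker sets (the anchor
#' group at the first half of the effect loci, the partner group at the
#' second half), so inter-population crosses segregate at all effect loci
#' while intra-population crosses segregate at almost none. A per-marker
#' additive effect vector (all favourable effects positive) is returned with
#' the panel.
#'
#' @param n_per_group inbred lines per subgroup.
#' @param n_markers total markers (half favour each group); must be even.
#' @param effect_size additive effect per favourable allele dose.
#' @param mislabel_rate per-line, per-locus probability of carrying the other
#'   group's allele (small residual within-group variation).
#' @param seed integer seed.
#' @return list with \code{panel} (a \code{founder_panel} with K = 2),
#'   \code{effects} (per-marker additive effects).
#' @export
simulate_complementary_panel <- function(n_per_group = 6, n_markers = 100,
                                         effect_size = 0.05,
                                         mislabel_rate = 0.05, seed = 1) {
  n_markers <- check_count(n_markers, "n_markers", min = 2L)
  stop_if(n_markers %% 2L != 0L, "'n_markers' must be even")
  set.seed(derive_seed(seed, "complementary"))
  half <- n_markers %/% 2L
  n <- 2L * n_per_group
  ## group 1 (anchor) fixed 2 at loci 1..half, 0 elsewhere; group 2 opposite
  base <- rbind(matrix(rep(c(2L, 0L), c(half, half)), n_per_group, n_markers, byrow = TRUE),
                matrix(rep(c(0L, 2L), c(half, half)), n_per_group, n_markers, byrow = TRUE))
  flip <- matrix(stats::runif(n * n_markers) < mislabel_rate, n, n_markers)
  dosage <- ifelse(flip, 2L - base, base)
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- sprintf("P%03d", seq_len(n))
  colnames(dosage) <- sprintf("M%05d", seq_len(n_markers))
  membership <- stats::setNames(rep(1:2, each = n_per_group), rownames(dosage))
  panel <- structure(list(dosage = dosage, membership = membership,
                          K = 2L, fst = NA_real_,
                          ancestral_freq = rep(0.5, n_markers),
                          group_freq = NULL),
                     class = "founder_panel")
  list(panel = panel,
       effects = stats::setNames(rep(effect_size, n_markers), colnames(dosage)))
}
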