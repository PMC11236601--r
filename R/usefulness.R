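#' Simulate doubled-haploid progeny of a cross between two inbreds
#'
#' Produces one recombinant gamete per progeny and chromosome under a
#' no-interference crossover process on the centimorgan scale and doubles it
#' to homozygosity. Under no interference the parental phase along a
#' chromosome is a two-state Markov chain at the marker positions, with
#' switch probability between adjacent markers given by Haldane's map
#' function r = (1 - exp(-2 d / 100)) / 2 for map distance d cM; the
#' starting phase is a fair coin. This is distributionally identical, at
#' the marker loci, to drawing a Poisson(length/100) crossover count with
#' uniform positions.
#'
#' @param parent1,parent2 named dosage vectors of the two inbred parents
#'   (entries 0 or 2).
#' @param map a \code{genetic_map}; markers absent from the map are excluded
#'   with a message.
#' @param n number of DH progeny (default 250).
#' @param seed integer seed.
#' @return a \code{dh_population}: list with \code{dosage} (n x mapped
#'   markers, entries 0/2), \code{parents}, \code{map_markers}.
#' @export
simulate_dh <- function(parent1, parent2, map, n = 250, seed = 1) {
  n <- check_count(n, "n")
  stop_if(any(!(parent1 %in% c(0, 2)) | !(parent2 %in% c(0, 2)), na.rm = TRUE),
          "heterozygous (or invalid) parent locus: parents must be fully inbred")
  ids <- names(parent1)
  stop_if(is.null(ids) || is.null(names(parent2)), "parents must be named dosage vectors")
  stop_if(!identical(ids, names(parent2)), "parents carry different marker sets")
  mapped <- intersect(ids, map$marker)
  if (length(mapped) < length(ids))
    message(sprintf("simulate_dh: excluding %d unmapped marker(s)",
                    length(ids) - length(mapped)))
  stop_if(length(mapped) == 0, "no parent markers on the map")
  mp <- map[match(mapped, map$marker), ]
  ord <- order(mp$chrom, mp$cM)
  mp <- mp[ord, ]
  p1 <- parent1[mp$marker] / 2   # allele (0/1) carried by parent 1
  p2 <- parent2[mp$marker] / 2

  set.seed(derive_seed(seed, "dh"))
  m <- nrow(mp)
  ## switch probability ahead of each marker (0 at each chromosome start)
  d <- c(0, diff(mp$cM))
  newchrom <- c(TRUE, diff(mp$chrom) != 0)
  r <- (1 - exp(-2 * d / 100)) / 2
  r[newchrom] <- 0.5  # independent phase coin at each chromosome start
  switches <- matrix(stats::runif(n * m), n, m) < rep(r, each = n)
  phase <- t(apply(switches, 1, cumsum)) %% 2  # 0 = parent1, 1 = parent2
  gamete <- sweep(1 - phase, 2, p1, "*") + sweep(phase, 2, p2, "*")
  dosage <- 2 * gamete
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sprintf("DH%04d", seq_len(n)), mp$marker)
  structure(list(dosage = dosage, map_markers = mp$marker,
                 parent_dosage = rbind(p1 = 2 * p1, p2 = 2 * p2)),
            class = "dh_population")
}

#' Genomic estimated breeding values of DH progeny
#'
#' value_i = dosage_i . alpha + site mean.
#'
#' @param pop a \code{dh_population} (or a dosage matrix).
#' @param effects per-marker additive effects: named vector or
#'   \code{marker_effects} data.frame covering the population's markers.
#' @param site_mean mean yield of the trial whose effects are used.
#' @return numeric vector of progeny values.
#' @export
gebv_score <- function(pop, effects, site_mean = 0) {
  dosage <- if (inherits(pop, "dh_population")) pop$dosage else as.matrix(pop)
  if (is.data.frame(effects))
    effects <- stats::setNames(effects$effect, effects$marker)
  stop_if(is.null(names(effects)), "effects must be named by marker")
  miss <- setdiff(colnames(dosage), names(effects))
  stop_if(length(miss) > 0, "no effect for marker(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  drop(dosage %*% effects[colnames(dosage)]) + site_mean
}

#' Selection intensity of truncation selection
#'
#' The standardised mean of the selected upper tail of a standard normal:
#' i = phi(z_p) / p with z_p the upper-p quantile. i(0.10) is about 1.755.
#'
#' @param p selected fraction in (0, 1).
#' @return the selection intensity.
#' @export
selection_intensity <- function(p) {
  check_scalar_number(p, "p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Usefulness criterion of a simulated cross
#'
#' UC = mu + i * h * sigma, with mu the progeny GEBV mean, sigma the
#' progeny standard deviation (n - 1 denominator), i the selection
#' intensity at selected fraction p and h the selection accuracy (1 when
#' selection is on the marker effects themselves).
#'
#' @param values progeny values from \code{\link{gebv_score}} (>= 2).
#' @param p selected fraction (default 0.10).
#' @param h selection accuracy (default 1).
#' @return list with \code{mu}, \code{sigma}, \code{i}, \code{h}, \code{uc}.
#' @export
usefulness_criterion <- function(values, p = 0.10, h = 1.0) {
  stop_if(length(values) < 2, "need at least two progeny values")
  mu <- mean(values)
  sigma <- stats::sd(values)
  i <- selection_intensity(p)
  list(mu = mu, sigma = sigma, i = i, h = h, uc = mu + i * h * sigma)
}

#' Usefulness of all crosses anchored on one genetic subgroup
#'
#' Simulates DH progeny for every cross of the anchor subgroup's parents
#' with every panel parent (anchor x anchor = intra-population, anchor x
#' other = inter-population), scores them with per-site marker effects and
#' computes the usefulness criterion per cross and site.
#'
#' @param panel a \code{founder_panel} with subgroup \code{membership}.
#' @param anchor_group subgroup label to anchor on.
#' @param effects named list (per site) of marker-effect vectors or
#'   \code{marker_effects} data.frames; a single vector is treated as one
#'   site.
#' @param map a \code{genetic_map}.
#' @param site_means numeric site means, recycled over sites.
#' @param n DH progeny per cross (default 250).
#' @param p,h selection fraction and accuracy.
#' @param seed integer seed.
#' @return a \code{uc_result} data.frame: cross, parent1, parent2, site,
#'   group_pair, category ("intra"/"inter"), mu, sigma, i, h, uc.
#' @export
compare_cross_sets <- function(panel, anchor_group, effects, map,
                               site_means = 0, n = 250, p = 0.10, h = 1.0,
                               seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  stop_if(!anchor_group %in% panel$membership, "anchor group '%s' absent",
          as.character(anchor_group))
  if (!is.list(effects)) effects <- list(site1 = effects)
  if (is.null(names(effects))) names(effects) <- paste0("site", seq_along(effects))
  site_means <- rep_len(site_means, length(effects))
  anchors <- names(panel$membership)[panel$membership == anchor_group]
  others <- rownames(panel$dosage)
  crosses <- expand.grid(parent1 = anchors, parent2 = others,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  crosses <- crosses[crosses$parent1 < crosses$parent2 |
                       !(crosses$parent2 %in% anchors), , drop = FALSE]
  crosses <- crosses[crosses$parent1 != crosses$parent2, , drop = FALSE]

  i_val <- selection_intensity(p)
  out <- vector("list", nrow(crosses))
  for (ci in seq_len(nrow(crosses))) {
    p1 <- crosses$parent1[ci]; p2 <- crosses$parent2[ci]
    pop <- simulate_dh(panel$dosage[p1, ], panel$dosage[p2, ], map, n = n,
                       seed = derive_seed(seed, paste0("cross", ci)))
    g1 <- panel$membership[p1]; g2 <- panel$membership[p2]
    rows <- lapply(seq_along(effects), function(s) {
      vals <- gebv_score(pop, effects[[s]], site_means[s])
      uc <- usefulness_criterion(vals, p = p, h = h)
      data.frame(cross = paste(p1, p2, sep = "x"), parent1 = p1, parent2 = p2,
                 site = names(effects)[s],
                 group_pair = paste(sort(c(g1, g2)), collapse = "x"),
                 category = ifelse(g1 == g2, "intra", "inter"),
                 mu = uc$mu, sigma = uc$sigma, i = i_val, h = h, uc = uc$uc,
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  class(res) <- c("uc_result", "data.frame")
  res
}
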