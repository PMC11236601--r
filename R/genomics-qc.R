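#' Marker quality control
#'
#' Retains markers whose heterozygote fraction (among non-missing calls) is
#' at most \code{max_het} and whose missing fraction is at most
#' \code{max_missing}; a marker strictly exceeding either threshold is
#' excluded. Column order is preserved.
#'
#' @param dosage individuals x markers matrix with entries in \{0, 1, 2\} and
#'   \code{NA} for missing calls.
#' @param max_het maximum tolerated heterozygote fraction (default 0.5).
#' @param max_missing maximum tolerated missing fraction (default 0.1).
#' @return the filtered dosage matrix (attribute \code{"removed"} lists the
#'   dropped marker ids).
#' @export
filter_markers <- function(dosage, max_het = 0.5, max_missing = 0.1) {
  dosage <- as.matrix(dosage)
  stop_if(nrow(dosage) == 0 || ncol(dosage) == 0, "empty genotype matrix")
  check_scalar_number(max_het, "max_het", 0, 1)
  check_scalar_number(max_missing, "max_missing", 0, 1)
  n <- nrow(dosage)
  n_miss <- colSums(is.na(dosage))
  n_het <- colSums(dosage == 1, na.rm = TRUE)
  het_frac <- ifelse(n_miss == n, 1, n_het / (n - n_miss))
  keep <- het_frac <= max_het & (n_miss / n) <= max_missing
  out <- dosage[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(dosage)[!keep]
  out
}

#' Prune one marker of every completely linked pair
#'
#' Drops monomorphic markers (zero dosage variance, for which r-squared is
#' undefined), then, scanning markers in input (genome) order, removes every
#' later marker whose squared Pearson correlation with a retained earlier
#' marker equals 1 (within \code{tol} of the correlation), so no surviving
#' pair is completely linked. Correlations use pairwise-complete
#' individuals.
#'
#' @param dosage individuals x markers matrix.
#' @param tol tolerance on |r| for declaring complete linkage.
#' @return pruned matrix; attributes \code{"n_monomorphic"} and
#'   \code{"removed"} record what was dropped.
#' @export
prune_complete_ld <- function(dosage, tol = 1e-12) {
  dosage <- as.matrix(dosage)
  stop_if(ncol(dosage) < 1, "need at least one marker")
  v <- apply(dosage, 2, stats::var, na.rm = TRUE)
  mono <- is.na(v) | v == 0
  n_mono <- sum(mono)
  if (n_mono > 0)
    message(sprintf("prune_complete_ld: dropping %d monomorphic marker(s)", n_mono))
  x <- dosage[, !mono, drop = FALSE]
  m <- ncol(x)
  if (m <= 1) {
    attr(x, "n_monomorphic") <- n_mono
    attr(x, "removed") <- colnames(dosage)[mono]
    return(x)
  }
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  keep <- rep(TRUE, m)
  for (j in 2:m) {
    earlier <- which(keep[seq_len(j - 1L)])
    if (any(abs(r[earlier, j]) >= 1 - tol, na.rm = TRUE)) keep[j] <- FALSE
  }
  out <- x[, keep, drop = FALSE]
  attr(out, "n_monomorphic") <- n_mono
  attr(out, "removed") <- c(colnames(dosage)[mono], colnames(x)[!keep])
  out
}

#' Rogers' genetic distance matrix
#'
#' For a biallelic locus an individual with dosage d is represented by the
#' within-individual allele-frequency vector ((2-d)/2, d/2); the per-locus
#' Rogers distance between two individuals reduces to |d1 - d2| / 2 and the
#' total distance is the mean over loci non-missing in both individuals.
#' Distances lie in [0, 1]: opposite homozygotes at every locus give 1.
#'
#' @param dosage individuals x markers matrix.
#' @return a symmetric distance matrix with zero diagonal and individual ids
#'   as dimnames.
#' @export
rogers_distance <- function(dosage) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  stop_if(n < 2, "need at least two individuals")
  obs <- !is.na(dosage)
  den <- tcrossprod(obs * 1)  # shared non-missing counts
  ## per-locus distance |d_i - d_j| / 2 accumulated through dosage-class
  ## indicator cross-products: |0-2| = 2, |0-1| = |1-2| = 1
  A0 <- (dosage == 0) & obs
  A1 <- (dosage == 1) & obs
  A2 <- (dosage == 2) & obs
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  x02 <- A0 %*% t(A2)
  x1o <- A1 %*% t(A0 + A2)
  num <- (2 * (x02 + t(x02)) + x1o + t(x1o)) / 2
  if (any(den[upper.tri(den)] == 0)) {
    bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    stop(sprintf("no shared non-missing loci for pair (%s, %s)",
                 rownames(dosage)[bad[1]], rownames(dosage)[bad[2]]),
         call. = FALSE)
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(dosage), rownames(dosage))
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the squared-distance matrix is double-centred
#' and eigendecomposed; coordinates are returned for axes with positive
#' eigenvalues, sorted by eigenvalue. Negative eigenvalues (non-Euclidean
#' distances) are reported but contribute no axes.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes to return (capped at the positive axes).
#' @return list with \code{coords} (individuals x axes), \code{eig} (all
#'   eigenvalues) and \code{prop_explained} over positive eigenvalues.
#' @export
pcoa_coords <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  stop_if(!isSymmetric(unname(d), tol = 1e-8), "'d' must be symmetric")
  n_axes <- check_count(n_axes, "n_axes")
  fit <- stats::cmdscale(stats::as.dist(d), k = min(n_axes, nrow(d) - 1L),
                         eig = TRUE)
  pos <- fit$eig > 1e-10 * max(abs(fit$eig))
  k <- min(n_axes, sum(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coords = coords, eig = fit$eig,
       prop_explained = pmax(fit$eig, 0) / sum(pmax(fit$eig, 0)))
}
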