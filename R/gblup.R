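#' Genomic relationship matrix (VanRaden method 1)
#'
#' K = Z Z' / (2 sum_j p_j (1 - p_j)) with Z the dosage matrix centred at
#' twice the allele frequency. Frequencies default to the observed ones;
#' missing dosages are mean-imputed per marker before centring (so imputed
#' cells contribute exactly zero to Z). For a fully inbred panel the mean
#' diagonal is near 2 (inbreeding f = 1 under this scaling).
#'
#' @param dosage individuals x markers matrix.
#' @param freq optional allele frequencies (length = markers); observed
#'   frequencies when NULL.
#' @return a \code{grm}: list with \code{K}, \code{freq}, \code{scale}
#'   (the 2 sum p(1-p) constant) and \code{Z} (centred dosage).
#' @export
compute_grm <- function(dosage, freq = NULL) {
  M <- as.matrix(dosage)
  if (is.null(freq)) freq <- colMeans(M, na.rm = TRUE) / 2
  stop_if(length(freq) != ncol(M), "freq length must equal marker count")
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- 2 * freq[idx[, 2]]
    message(sprintf("compute_grm: mean-imputed %d missing dosage cells", nrow(idx)))
  }
  sc <- 2 * sum(freq * (1 - freq))
  stop_if(sc <= 0, "all markers monomorphic: zero VanRaden scaling constant")
  Z <- sweep(M, 2, 2 * freq)
  K <- tcrossprod(Z) / sc
  dimnames(K) <- list(rownames(M), rownames(M))
  structure(list(K = K, freq = freq, scale = sc, Z = Z), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals, scaling 2*sum p(1-p) = %.3f, mean diag = %.3f\n",
              nrow(x$K), x$scale, mean(diag(x$K))))
  invisible(x)
}

#' Genomic BLUP of parental and hybrid additive effects
#'
#' Solves the mixed model y = X b + M g + e with parental effects
#' g ~ N(0, K sigma2_a), where M maps each observation onto its parents
#' (the hybrid-to-parent incidence for hybrid-level data, or an identity
#' selection for parent-level data). Variances are REML-estimated when not
#' supplied. Hybrid additive values are the sums of the two parental GEBVs.
#'
#' @param y numeric phenotypes (hybrid BLUEs/BLUPs or parent-level values).
#' @param K a \code{grm} (or plain PSD matrix) over parents.
#' @param design observations x parents incidence matrix; rows of a hybrid
#'   table sum to 2. Defaults to matching \code{names(y)} against
#'   \code{rownames(K)} (parent-level identity).
#' @param variances optional c(sigma2_a, sigma2_e); REML-estimated if NULL.
#' @param X fixed-effect design (default an intercept).
#' @return a \code{gblup_fit}: \code{gebv} (parents), \code{hybrid_additive}
#'   (when the design has hybrid rows), \code{sigma2}, \code{beta},
#'   \code{fit} (the underlying \code{reml_fit}, NULL when variances were
#'   supplied), \code{ridge_applied}.
#' @export
gblup_solve <- function(y, K, design = NULL, variances = NULL, X = NULL) {
  Kmat <- if (inherits(K, "grm")) K$K else as.matrix(K)
  np <- nrow(Kmat)
  if (is.null(design)) {
    stop_if(is.null(names(y)) || is.null(rownames(Kmat)),
            "need a design matrix, or names on y and K")
    miss <- setdiff(names(y), rownames(Kmat))
    stop_if(length(miss) > 0, "parents missing from K: %s", paste(miss, collapse = ", "))
    design <- indicator(factor(names(y), levels = rownames(Kmat)))
  }
  design <- as.matrix(design)
  stop_if(ncol(design) != np, "design columns must match K")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  ridge_applied <- FALSE
  ev_min <- min(eigen(Kmat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    Kmat <- Kmat + diag(1e-8, np)
    ridge_applied <- TRUE
    warning("near-singular K: ridge 1e-8 added to the diagonal")
  }

  fit <- NULL
  if (is.null(variances)) {
    fit <- reml_mixed(y, X, Zlist = list(additive = design), Klist = list(Kmat))
    sigma2 <- c(a = unname(fit$sigma2["additive"]),
                e = unname(fit$sigma2["residual"]))
    beta <- fit$beta
    gebv <- fit$u$additive
  } else {
    sigma2 <- c(a = variances[1], e = variances[2])
    V <- sigma2["a"] * design %*% Kmat %*% t(design) + diag(sigma2["e"], n)
    Vi <- chol2inv(chol(V))
    XtViX <- crossprod(X, Vi %*% X)
    beta <- drop(solve(XtViX, crossprod(X, Vi %*% y)))
    r <- y - X %*% beta
    gebv <- drop(sigma2["a"] * Kmat %*% crossprod(design, Vi %*% r))
  }
  names(gebv) <- rownames(Kmat)
  hybrid_additive <- if (any(rowSums(design) > 1)) drop(design %*% gebv) else NULL
  structure(list(gebv = gebv, hybrid_additive = hybrid_additive,
                 sigma2 = sigma2, beta = beta, fit = fit,
                 ridge_applied = ridge_applied),
            class = "gblup_fit")
}

#' Backsolve per-marker additive effects from parental GEBVs
#'
#' With K = Z Z' / c from \code{\link{compute_grm}}, marker effects are
#' alpha = Z' K^{-1} g / c; when K has full rank from these markers the
#' reconstruction Z alpha equals g exactly. A rank-deficient K is inverted
#' by pseudo-inverse with the rank reported.
#'
#' @param gebv named parental GEBV vector.
#' @param grm the \code{grm} the GEBVs were predicted under.
#' @return a \code{marker_effects} data.frame: marker, effect; attribute
#'   \code{"rank"} gives the rank used for inversion.
#' @export
backsolve_markers <- function(gebv, grm) {
  stopifnot(inherits(grm, "grm"))
  K <- grm$K
  stop_if(length(gebv) != nrow(K), "gebv length must match the GRM")
  ee <- eigen(K, symmetric = TRUE)
  pos <- ee$values > 1e-10 * max(ee$values)
  rank <- sum(pos)
  if (rank < nrow(K))
    message(sprintf("backsolve_markers: K rank %d < %d, using pseudo-inverse",
                    rank, nrow(K)))
  Kinv_g <- ee$vectors[, pos, drop = FALSE] %*%
    ((crossprod(ee$vectors[, pos, drop = FALSE], gebv)) / ee$values[pos])
  alpha <- drop(crossprod(grm$Z, Kinv_g)) / grm$scale
  out <- data.frame(marker = colnames(grm$Z), effect = alpha,
                    stringsAsFactors = FALSE)
  attr(out, "rank") <- rank
  out
}

#' Flag top markers and measure cross-site effect concordance
#'
#' Flags the top fraction of markers by absolute effect (ties broken by
#' marker order) and annotates genome coordinates for Manhattan-style
#' plotting. When a second site's effects are supplied, cross-site
#' concordance (sign-agreement fraction and Pearson correlation) is
#' attached.
#'
#' @param effects \code{marker_effects} data.frame (or named vector).
#' @param map optional \code{genetic_map} for coordinates.
#' @param top_fraction fraction of markers to flag (default 0.10).
#' @param other optional second effect vector for concordance.
#' @return data.frame marker, chrom, cM, effect, top (logical), ordered by
#'   genome position when a map is given; attribute \code{"concordance"}
#'   holds \code{sign_agreement} and \code{correlation} when \code{other}
#'   is supplied.
#' @export
effect_profile <- function(effects, map = NULL, top_fraction = 0.10,
                           other = NULL) {
  if (is.data.frame(effects)) {
    eff <- effects$effect
    ids <- effects$marker
  } else {
    eff <- as.numeric(effects)
    ids <- names(effects)
  }
  check_scalar_number(top_fraction, "top_fraction", 0, 1)
  m <- length(eff)
  n_top <- floor(m * top_fraction)
  top <- rep(FALSE, m)
  if (n_top > 0)
    top[order(-abs(eff), seq_len(m))[seq_len(n_top)]] <- TRUE
  out <- data.frame(marker = ids, effect = eff, top = top,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    i <- match(out$marker, map$marker)
    out$chrom <- map$chrom[i]
    out$cM <- map$cM[i]
    out <- out[order(out$chrom, out$cM), ]
  }
  if (!is.null(other)) {
    o <- if (is.data.frame(other)) other$effect else as.numeric(other)
    stop_if(length(o) != m, "effect vectors differ in length")
    nz <- eff != 0 | o != 0
    attr(out, "concordance") <- list(
      sign_agreement = mean(sign(eff[nz]) == sign(o[nz])),
      correlation = stats::cor(eff, o))
  }
  out
}
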