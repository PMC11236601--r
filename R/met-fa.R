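#' Weighted factor analysis of additive effects across trial sites
#'
#' Models the between-site additive genetic covariance as G = Lambda
#' Lambda' + Psi (factor-analytic of order k) from a genotype x site table
#' of stage-one additive BLUPs, which may be sparse (a genotype absent from
#' a site is NA). Estimation is EM on the Gaussian likelihood of each
#' genotype's observed subvector; optional per-entry precision weights w
#' scale the specific variance of an entry to psi_s / w. Loadings are
#' rotated to the lower-triangular identification (zeros above the
#' diagonal, positive diagonal).
#'
#' @param effects genotypes x sites numeric matrix (NA = genotype not
#'   evaluated at that site); column names are site ids.
#' @param k factor order (>= 1, < number of sites).
#' @param weights optional matrix of positive weights, same shape.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param center subtract site means first (default TRUE).
#' @return an \code{fa_model}: \code{loadings} (sites x k), \code{psi},
#'   \code{G}, \code{loglik}, \code{ll_trace}, \code{converged},
#'   \code{n_genotypes}, \code{sites}.
#' @export
fit_fa <- function(effects, k, weights = NULL, max_iter = 2000, tol = 1e-8,
                   center = TRUE) {
  X <- as.matrix(effects)
  S <- ncol(X)
  k <- check_count(k, "k")
  stop_if(k >= S, "factor order k = %d must be below the number of sites (%d)",
          k, S)
  if (is.null(colnames(X))) colnames(X) <- paste0("S", seq_len(S))
  if (is.null(weights)) weights <- matrix(1, nrow(X), S)
  weights <- as.matrix(weights)
  stop_if(any(weights <= 0, na.rm = TRUE), "weights must be positive")

  ## drop sites sharing fewer than 2 genotypes with every other site
  obs <- !is.na(X)
  share <- crossprod(obs * 1)
  diag(share) <- -Inf
  lonely <- apply(share, 1, max) < 2
  if (any(lonely)) {
    warning(sprintf("excluding site(s) with <2 shared genotypes: %s",
                    paste(colnames(X)[lonely], collapse = ", ")))
    X <- X[, !lonely, drop = FALSE]
    weights <- weights[, !lonely, drop = FALSE]
    S <- ncol(X)
    stop_if(k >= S, "factor order too large after dropping sparse sites")
  }
  if (center) X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  weights <- weights[keep, , drop = FALSE]
  G_n <- nrow(X)

  ## init from eigen-decomposition of the pairwise-complete covariance
  Sg <- stats::cov(X, use = "pairwise.complete.obs")
  Sg[is.na(Sg)] <- 0
  Sg <- (Sg + t(Sg)) / 2
  ee <- eigen(Sg, symmetric = TRUE)
  L <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ee$values[seq_len(k)], 1e-6)), k)
  psi <- pmax(diag(Sg) - rowSums(L^2), 0.05 * pmax(diag(Sg), 1e-6))

  obs_idx <- lapply(seq_len(G_n), function(g) which(!is.na(X[g, ])))
  ll_trace <- numeric(0)
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sum_xf <- matrix(0, S, k)           # per-site sum of w * x * E[f]'
    sum_ff <- array(0, c(S, k, k))      # per-site sum of w * E[ff']
    sum_x2 <- numeric(S)
    sum_w <- numeric(S)
    ll_new <- 0
    for (g in seq_len(G_n)) {
      O <- obs_idx[[g]]
      x <- X[g, O]
      w <- weights[g, O]
      LO <- L[O, , drop = FALSE]
      Sig <- tcrossprod(LO) + diag(psi[O] / w, length(O))
      cS <- chol(Sig)
      ix <- backsolve(cS, backsolve(cS, x, transpose = TRUE))  # Sig^-1 x
      B <- t(backsolve(cS, backsolve(cS, LO, transpose = TRUE)))  # k x |O|, L' Sig^-1
      Ef <- drop(B %*% x)
      Vf <- diag(k) - B %*% LO
      EffT <- Vf + tcrossprod(Ef)
      ll_new <- ll_new - 0.5 * (length(O) * log(2 * pi) +
                                  2 * sum(log(diag(cS))) + sum(x * ix))
      for (s in seq_along(O)) {
        ss <- O[s]
        sum_xf[ss, ] <- sum_xf[ss, ] + w[s] * x[s] * Ef
        sum_ff[ss, , ] <- sum_ff[ss, , ] + w[s] * EffT
        sum_x2[ss] <- sum_x2[ss] + w[s] * x[s]^2
        sum_w[ss] <- sum_w[ss] + w[s]
      }
    }
    ## M-step
    for (s in seq_len(S)) {
      if (sum_w[s] == 0) next
      A <- matrix(sum_ff[s, , ], k, k)
      L[s, ] <- solve(A + diag(1e-10, k), sum_xf[s, ])
      psi[s] <- max((sum_x2[s] - sum(L[s, ] * sum_xf[s, ])) / sum_w[s], 1e-10)
    }
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged)
    warning(sprintf("fit_fa: EM not converged after %d iterations", max_iter))

  ## rotate to lower-triangular Lambda with positive diagonal
  if (k > 1) {
    qrL <- qr(t(L))
    Qm <- qr.Q(qrL)
    L <- t(qr.R(qrL))
    L <- L %*% diag(sign(diag(L)[seq_len(k)] + (diag(L)[seq_len(k)] == 0)), k)
  } else if (L[1, 1] < 0) L <- -L
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("F", seq_len(k))
  G <- tcrossprod(L) + diag(psi, S)
  dimnames(G) <- list(colnames(X), colnames(X))
  structure(list(loadings = L, psi = stats::setNames(psi, colnames(X)),
                 G = G, k = k, loglik = ll, ll_trace = ll_trace,
                 converged = converged, n_genotypes = G_n,
                 sites = colnames(X)),
            class = "fa_model")
}

#' Additive genetic correlation between trial sites
#'
#' Converts the factor-analytic covariance G = Lambda Lambda' + Psi into a
#' correlation matrix. Sites with zero genetic variance get NA correlations
#' with a warning.
#'
#' @param model an \code{fa_model} (or a covariance matrix).
#' @return sites x sites correlation matrix with unit diagonal.
#' @export
genetic_correlation <- function(model) {
  G <- if (inherits(model, "fa_model")) model$G else as.matrix(model)
  v <- diag(G)
  if (any(v <= 0)) {
    warning("site(s) with zero genetic variance: correlations set to NA")
    bad <- v <= 0
    v[bad] <- NA
  }
  C <- G / sqrt(outer(v, v))
  diag(C) <- ifelse(is.na(v), NA, 1)
  C
}

#' Percentage of additive genetic variance explained by leading factors
#'
#' Per site i the first m factors explain
#' 100 * sum_{f<=m} lambda_if^2 / (sum_f lambda_if^2 + psi_i) percent of the
#' site's additive variance. The overall summary is reported both as the
#' unweighted mean across sites and as the variance-weighted mean.
#'
#' @param model an \code{fa_model}.
#' @param m number of leading factors (0 <= m <= k).
#' @return list with \code{per_site} (percent per site), \code{overall}
#'   (unweighted mean percent), \code{overall_weighted} (variance-weighted).
#' @export
variance_explained <- function(model, m) {
  stopifnot(inherits(model, "fa_model"))
  m <- check_count(m, "m", min = 0L)
  stop_if(m > model$k, "m = %d exceeds the factor order k = %d", m, model$k)
  tot <- rowSums(model$loadings^2) + model$psi
  expl <- if (m == 0) rep(0, length(tot))
          else rowSums(model$loadings[, seq_len(m), drop = FALSE]^2)
  per_site <- 100 * expl / tot
  list(per_site = per_site,
       overall = mean(per_site),
       overall_weighted = 100 * sum(expl) / sum(tot))
}

#' Cluster trial sites from their additive genetic correlation
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' 1 - correlation. The number of clusters is either fixed by the caller or
#' chosen automatically at the largest relative gap between successive
#' merge heights; if all merge heights are (numerically) equal there is no
#' structure and a single cluster is returned with a warning.
#'
#' @param corr sites x sites correlation matrix.
#' @param n_clusters integer, or NULL for the automatic rule.
#' @param method linkage method for \code{\link[stats]{hclust}}.
#' @return an \code{env_clustering}: list with \code{labels} (named integer
#'   cluster per site), \code{n_clusters}, \code{tree} (hclust),
#'   \code{heights}.
#' @export
cluster_sites <- function(corr, n_clusters = NULL, method = "average") {
  corr <- as.matrix(corr)
  S <- nrow(corr)
  stop_if(S < 2, "need at least two sites")
  if (!is.null(n_clusters)) {
    n_clusters <- check_count(n_clusters, "n_clusters")
    stop_if(n_clusters > S, "n_clusters = %d exceeds the %d sites", n_clusters, S)
  }
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = method)
  h <- hc$height
  if (is.null(n_clusters)) {
    if (max(h) - min(h) <= 1e-8 * max(abs(h), 1)) {
      warning("degenerate merge heights: no cluster structure, returning 1 cluster")
      n_clusters <- 1L
    } else if (S == 2) {
      n_clusters <- 2L
    } else {
      gaps <- (h[-1] - h[-length(h)]) / pmax(h[-length(h)], 1e-12)
      n_clusters <- S - which.max(gaps)
    }
  }
  labels <- stats::cutree(hc, k = n_clusters)
  structure(list(labels = labels, n_clusters = n_clusters, tree = hc,
                 heights = h, method = method),
            class = "env_clustering")
}
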