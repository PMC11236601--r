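#' Maximum-likelihood admixture estimation
#'
#' Fits the admixture model for unphased biallelic dosages: individual i's
#' dosage at marker j is Binomial(2, f_ij) with f_ij = q_i . p_j, where the
#' rows of Q (individuals x K) are ancestry proportions on the simplex and P
#' (K x markers) holds ancestral allele frequencies. The binomial
#' log-likelihood is maximised by alternating EM updates of Q and P
#' (guaranteed non-decreasing); missing dosages are excluded from the
#' likelihood.
#'
#' @param dosage individuals x markers matrix in \{0, 1, 2\} with NA missing.
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed (initialisation).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param mask optional logical matrix; TRUE cells are held out of the
#'   likelihood (used by cross-validation).
#' @return an \code{admixture_fit}: list with \code{Q}, \code{P}, \code{K},
#'   \code{loglik}, \code{ll_trace}, \code{converged}, \code{iterations}.
#' @export
admixture_fit <- function(dosage, K, seed = 1, max_iter = 2000, tol = 1e-6,
                          mask = NULL) {
  dosage <- as.matrix(dosage)
  K <- check_count(K, "K")
  n <- nrow(dosage); m <- ncol(dosage)
  stop_if(n == 0 || m == 0, "empty genotype matrix")
  W <- !is.na(dosage)
  if (!is.null(mask)) W <- W & !mask
  D <- dosage; D[!W] <- 0
  Wd <- W * 1
  Dm <- D * Wd
  D2m <- (2 - D) * Wd
  Mi <- rowSums(Wd)
  stop_if(any(Mi == 0), "individual with no observed markers")
  eps <- 1e-6

  set.seed(derive_seed(seed, "admixture"))
  ## initialise from k-means on dosage rows (mean-imputed)
  X <- dosage
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  if (K > 1) {
    km <- suppressWarnings(stats::kmeans(X, centers = K, nstart = 5))
    Q <- matrix(0.2 / max(K - 1, 1), n, K)
    Q[cbind(seq_len(n), km$cluster)] <- 0.8
    P <- pmin(pmax(km$centers / 2, eps), 1 - eps)
  } else {
    Q <- matrix(1, n, 1)
    P <- matrix(pmin(pmax(colMeans(X) / 2, eps), 1 - eps), 1, m)
  }

  ll_of <- function(Q, P) {
    Fm <- pmin(pmax(Q %*% P, eps), 1 - eps)
    sum(Dm * log(Fm) + D2m * log1p(-Fm))
  }
  ll <- ll_of(Q, P)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Fm <- pmin(pmax(Q %*% P, eps), 1 - eps)
    RA <- Dm / Fm          # d / f on observed cells
    RB <- D2m / (1 - Fm)   # (2-d) / (1-f)
    Anum <- matrix(0, n, K); Pnew <- P
    for (k in seq_len(K)) {
      ak <- (RA * outer(Q[, k], P[k, ]))        # expected copies from pop k
      bk <- (RB * outer(Q[, k], 1 - P[k, ]))
      Pnew[k, ] <- colSums(ak) / pmax(colSums(ak) + colSums(bk), 1e-300)
      Anum[, k] <- rowSums(ak) + rowSums(bk)
    }
    P <- pmin(pmax(Pnew, eps), 1 - eps)
    Q <- Anum / (2 * Mi)
    Q <- pmax(Q, 1e-9)
    Q <- Q / rowSums(Q)
    ll_new <- ll_of(Q, P)
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged)
    warning(sprintf("admixture_fit: not converged after %d iterations", iter))
  dimnames(Q) <- list(rownames(dosage), paste0("K", seq_len(K)))
  dimnames(P) <- list(paste0("K", seq_len(K)), colnames(dosage))
  structure(list(Q = Q, P = P, K = K, loglik = ll, ll_trace = ll_trace,
                 converged = converged, iterations = iter),
            class = "admixture_fit")
}

#' Select the number of ancestral populations by masked-entry cross-validation
#'
#' Partitions the observed genotype cells into folds; for each fold the
#' masked cells are held out, the admixture model is fitted on the remainder
#' for each candidate K, and held-out dosages are scored by squared error
#' against their fitted expectation 2 q_i . p_j. The K minimising the mean
#' prediction error is returned.
#'
#' @param dosage individuals x markers matrix.
#' @param k_min,k_max candidate range of K.
#' @param folds number of cross-validation folds.
#' @param seed integer seed.
#' @param max_iter,tol passed to \code{\link{admixture_fit}}.
#' @return list with \code{K} (selected), \code{cv_error} (named vector over
#'   candidates) and \code{fold_error} (folds x candidates matrix).
#' @export
select_K_cv <- function(dosage, k_min = 2, k_max = 10, folds = 3, seed = 1,
                        max_iter = 150, tol = 1e-3) {
  dosage <- as.matrix(dosage)
  k_min <- check_count(k_min, "k_min"); k_max <- check_count(k_max, "k_max")
  stop_if(k_min > k_max, "k_min > k_max")
  folds <- check_count(folds, "folds", min = 2L)
  obs <- which(!is.na(dosage))
  stop_if(length(obs) < folds, "too few observed cells for %d folds", folds)
  set.seed(derive_seed(seed, "cvK"))
  fold_id <- sample(rep_len(seq_len(folds), length(obs)))
  ks <- k_min:k_max
  fe <- matrix(NA_real_, folds, length(ks),
               dimnames = list(NULL, paste0("K", ks)))
  for (f in seq_len(folds)) {
    cells <- obs[fold_id == f]
    stop_if(length(cells) == 0, "fold %d has no masked entries", f)
    mask <- matrix(FALSE, nrow(dosage), ncol(dosage))
    mask[cells] <- TRUE
    for (ki in seq_along(ks)) {
      fit <- suppressWarnings(
        admixture_fit(dosage, ks[ki], seed = derive_seed(seed, paste0("cv", f, "k", ki)),
                      max_iter = max_iter, tol = tol, mask = mask))
      pred <- 2 * (fit$Q %*% fit$P)
      fe[f, ki] <- mean((dosage[cells] - pred[cells])^2)
    }
  }
  cv <- colMeans(fe)
  list(K = ks[which.min(cv)], cv_error = cv, fold_error = fe)
}
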