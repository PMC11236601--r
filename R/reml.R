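#' Average-information REML for Gaussian variance-component models
#'
#' Fits y = X b + sum_k Z_k u_k + e with u_k ~ N(0, sigma2_k K_k) and
#' e ~ N(0, sigma2_e R), maximising the restricted likelihood by
#' average-information (AI) updates with step-halving and a guaranteed-ascent
#' EM fallback; components are floored at \code{floor}. A non-identity
#' residual correlation R is handled by Cholesky whitening, so the iteration
#' itself always sees an iid residual.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (must be full column rank).
#' @param Zlist named list of random-effect design matrices (n x q_k).
#' @param Klist optional list of covariance matrices per term (NULL entries
#'   mean identity).
#' @param R optional residual correlation matrix (n x n).
#' @param init optional named starting values for the variance components
#'   (terms then \code{residual}).
#' @param maxit maximum iterations.
#' @param tol_ll convergence tolerance on the REML log-likelihood change.
#' @param tol_par convergence tolerance on relative component change.
#' @param floor lower bound for variance components.
#' @return a \code{reml_fit}: variance components \code{sigma2}, fixed
#'   effects \code{beta}, BLUPs \code{u} with \code{pev} and
#'   \code{reliability} per term, \code{loglik}, \code{ll_trace},
#'   \code{converged}, \code{iterations}, and \code{n_params}.
#' @export
reml_mixed <- function(y, X, Zlist, Klist = NULL, R = NULL, init = NULL,
                       maxit = 200, tol_ll = 1e-6, tol_par = 1e-5,
                       floor = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stop_if(nrow(X) != n, "X rows must match length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular fixed design; aliased columns: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  stop_if(length(Zlist) < 1, "need at least one random term")
  if (is.null(names(Zlist)) || any(names(Zlist) == ""))
    names(Zlist) <- paste0("term", seq_along(Zlist))
  if (is.null(Klist)) Klist <- vector("list", length(Zlist))

  logdetR <- 0
  if (!is.null(R)) {
    LR <- chol(R)  # R = t(LR) %*% LR
    logdetR <- 2 * sum(log(diag(LR)))
    y <- backsolve(LR, y, transpose = TRUE)
    Xn <- colnames(X)
    X <- backsolve(LR, X, transpose = TRUE)
    colnames(X) <- Xn
    Zlist <- lapply(Zlist, function(Z) {
      Zw <- backsolve(LR, as.matrix(Z), transpose = TRUE)
      colnames(Zw) <- colnames(Z)
      Zw
    })
  }
  Zlist <- lapply(Zlist, as.matrix)
  nt <- length(Zlist)
  ## n x n covariance contribution of each term
  Vdot <- vector("list", nt + 1L)
  for (k in seq_len(nt)) {
    Zk <- Zlist[[k]]
    Vdot[[k]] <- if (is.null(Klist[[k]])) tcrossprod(Zk)
                 else Zk %*% Klist[[k]] %*% t(Zk)
  }
  Vdot[[nt + 1L]] <- diag(n)
  qk <- c(vapply(Zlist, ncol, 1L), n)
  labels <- c(names(Zlist), "residual")

  vy <- stats::var(y)
  theta <- if (!is.null(init)) pmax(as.numeric(init[labels]), floor)
           else rep(vy / (nt + 1), nt + 1L)
  names(theta) <- labels

  eval_at <- function(theta) {
    V <- Reduce(`+`, Map(`*`, Vdot, theta))
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cXtViX <- chol(XtViX)
    B <- chol2inv(cXtViX)      # (X'V^-1X)^-1
    Py <- Vi %*% y - ViX %*% (B %*% crossprod(ViX, y))
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtViX))) +
                    sum(y * Py) + logdetR)
    list(Vi = Vi, ViX = ViX, B = B, Py = Py, ll = ll)
  }

  st <- eval_at(theta)
  stop_if(is.null(st), "initial covariance matrix not positive definite")
  ll_trace <- st$ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    ## P M = Vi M - ViX B X'Vi M applied to the Vdot[[k]] %*% Py vectors
    Wk <- lapply(Vdot, function(Vd) Vd %*% st$Py)
    PWk <- lapply(Wk, function(w)
      st$Vi %*% w - st$ViX %*% (st$B %*% crossprod(st$ViX, w)))
    score <- numeric(nt + 1L)
    for (k in seq_len(nt + 1L)) {
      trPV <- sum(st$Vi * Vdot[[k]]) -
        sum(st$ViX * (Vdot[[k]] %*% (st$ViX %*% st$B)))
      score[k] <- -0.5 * (trPV - sum(st$Py * Wk[[k]]))
    }
    AI <- matrix(0, nt + 1L, nt + 1L)
    for (j in seq_len(nt + 1L))
      for (k in j:(nt + 1L))
        AI[j, k] <- AI[k, j] <- 0.5 * sum(Wk[[j]] * PWk[[k]])

    step <- tryCatch(solve(AI + diag(1e-10, nt + 1L), score),
                     error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      fac <- 1
      for (h in 1:5) {
        cand <- pmax(theta + fac * step, floor)
        stc <- eval_at(cand)
        if (!is.null(stc) && stc$ll >= st$ll - 1e-10) {
          theta_new <- cand; st_new <- stc; accepted <- TRUE
          break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {
      ## EM-REML update: guaranteed not to decrease the likelihood
      em <- theta
      for (k in seq_len(nt + 1L)) {
        trPV <- sum(st$Vi * Vdot[[k]]) -
          sum(st$ViX * (Vdot[[k]] %*% (st$ViX %*% st$B)))
        em[k] <- theta[k] + theta[k]^2 * (sum(st$Py * Wk[[k]]) - trPV) / qk[k]
      }
      theta_new <- pmax(em, floor)
      st_new <- eval_at(theta_new)
      if (is.null(st_new)) break
    }
    dll <- st_new$ll - st$ll
    dpar <- max(abs(theta_new - theta) / pmax(abs(theta), floor))
    theta <- theta_new
    st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (abs(dll) < tol_ll && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("reml_mixed: not converged after %d iterations", iter))

  beta <- drop(st$B %*% crossprod(st$ViX, y))
  names(beta) <- colnames(X)
  u <- pev <- rel <- vector("list", nt)
  names(u) <- names(pev) <- names(rel) <- names(Zlist)
  for (k in seq_len(nt)) {
    Zk <- Zlist[[k]]
    Kk <- Klist[[k]]
    KZt <- if (is.null(Kk)) t(Zk) else Kk %*% t(Zk)   # q_k x n
    u[[k]] <- drop(theta[k] * (KZt %*% st$Py))
    ## PEV = sigma2 K - sigma2^2 K Z' P Z K  (diagonal)
    PM <- st$Vi %*% t(KZt) - st$ViX %*% (st$B %*% crossprod(st$ViX, t(KZt)))
    kdiag <- if (is.null(Kk)) rep(1, ncol(Zk)) else diag(Kk)
    pev[[k]] <- pmax(theta[k] * kdiag - theta[k]^2 * colSums(t(KZt) * PM), 0)
    rel[[k]] <- ifelse(theta[k] * kdiag > 0,
                       pmin(pmax(1 - pev[[k]] / (theta[k] * kdiag), 0), 1), NA)
    lv <- colnames(Zk)
    if (!is.null(lv)) {
      names(u[[k]]) <- names(pev[[k]]) <- names(rel[[k]]) <- lv
    }
  }
  structure(list(sigma2 = theta, beta = beta, u = u, pev = pev,
                 reliability = rel, loglik = st$ll, ll_trace = ll_trace,
                 converged = converged, iterations = iter,
                 n_params = nt + 1L),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit: logLik =", format(x$loglik, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$sigma2, 5))
  invisible(x)
}

## Residual correlation over arbitrary plot coordinates:
## R_ij = rho_r^|row_i - row_j| * rho_c^|col_i - col_j|
ar1xar1_corr <- function(row, col, rho_r, rho_c) {
  ar1_corr(row, rho_r) * ar1_corr(col, rho_c)
}

#' Profile REML over separable AR1 x AR1 residual autocorrelation
#'
#' Maximises the REML log-likelihood over (rho_r, rho_c) by Nelder-Mead on
#' the atanh scale, with the variance components re-estimated by
#' \code{\link{reml_mixed}} (warm-started) at every candidate.
#'
#' @param y,X,Zlist,Klist as in \code{\link{reml_mixed}}.
#' @param row,col plot coordinates.
#' @param rho_init starting autocorrelations.
#' @param inner_maxit iteration cap for the inner REML fits.
#' @param outer_maxit evaluation cap for the Nelder-Mead search.
#' @return the best \code{reml_fit}, with \code{rho} attached and
#'   \code{n_params} incremented by 2.
#' @export
reml_ar1 <- function(y, X, Zlist, Klist = NULL, row, col,
                     rho_init = c(0.3, 0.3), inner_maxit = 60,
                     outer_maxit = 40) {
  warm <- NULL
  best <- list(ll = -Inf, fit = NULL, rho = rho_init)
  negll <- function(par) {
    rho <- tanh(par)
    Rm <- ar1xar1_corr(row, col, rho[1], rho[2])
    fit <- tryCatch(
      suppressWarnings(reml_mixed(y, X, Zlist, Klist, R = Rm, init = warm,
                                  maxit = inner_maxit)),
      error = function(e) NULL)
    if (is.null(fit)) return(1e10)
    warm <<- fit$sigma2
    if (fit$loglik > best$ll)
      best <<- list(ll = fit$loglik, fit = fit, rho = rho)
    -fit$loglik
  }
  opt <- stats::optim(atanh(pmin(pmax(rho_init, -0.9), 0.9)), negll,
                      method = "Nelder-Mead",
                      control = list(maxit = outer_maxit, reltol = 1e-6))
  fit <- best$fit
  stop_if(is.null(fit), "AR1 profile likelihood failed at every candidate")
  fit$rho <- stats::setNames(best$rho, c("rho_r", "rho_c"))
  fit$n_params <- fit$n_params + 2L
  fit
}
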