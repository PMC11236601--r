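#' Hybrid-to-parent additive incidence matrix
#'
#' Each F1 hybrid of two inbred parents transmits one genome from each, so
#' its additive value is the sum of the two parental general combining
#' abilities: the incidence row for a hybrid has a unit entry in its male
#' and in its female parent's column. Reciprocal crosses get identical rows.
#'
#' @param crosses data.frame with columns \code{hybrid}, \code{male},
#'   \code{female} (or a \code{cross_plan}).
#' @param parents optional character vector fixing the parent column order;
#'   defaults to the parents appearing in the crosses.
#' @return hybrids x parents incidence matrix with row sums 2.
#' @export
build_hybrid_additive_design <- function(crosses, parents = NULL) {
  if (inherits(crosses, "cross_plan")) crosses <- crosses$crosses
  stopifnot(all(c("hybrid", "male", "female") %in% names(crosses)))
  if (is.null(parents)) parents <- unique(c(crosses$male, crosses$female))
  bad <- setdiff(unique(c(crosses$male, crosses$female)), parents)
  stop_if(length(bad) > 0, "unknown parent(s): %s", paste(bad, collapse = ", "))
  Tm <- matrix(0, nrow(crosses), length(parents),
               dimnames = list(crosses$hybrid, parents))
  Tm[cbind(seq_len(nrow(crosses)), match(crosses$male, parents))] <-
    Tm[cbind(seq_len(nrow(crosses)), match(crosses$male, parents))] + 1
  Tm[cbind(seq_len(nrow(crosses)), match(crosses$female, parents))] <-
    Tm[cbind(seq_len(nrow(crosses)), match(crosses$female, parents))] + 1
  Tm
}

## indicator matrix of a factor, named columns
indicator <- function(f, levels = NULL) {
  f <- factor(f, levels = if (is.null(levels)) sort(unique(f)) else levels)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Fit a single-trial linear mixed model
#'
#' The base model fits trial design factors (row, column, block) and hybrid
#' genetic effects as random, and check cultivars as fixed; hybrids share a
#' common intercept. With \code{genetic = "additive"} the hybrid effect is
#' partitioned into an additive part (plot mapped onto its two parents, with
#' an optional relationship matrix among parents) and a non-additive part
#' indexed by hybrid identity. With \code{spatial = "ar1"} the residual is
#' AR1 x AR1 over the row/column grid, with the autocorrelations profiled.
#'
#' @param pheno plot table for one site: columns \code{row}, \code{col},
#'   \code{block}, \code{entry}, \code{male}, \code{female},
#'   \code{is_check}, \code{yield}.
#' @param genetic \code{"hybrid"} (single genetic term) or \code{"additive"}
#'   (additive + non-additive partition).
#' @param rel optional relationship matrix: over parents when
#'   \code{genetic = "additive"}, over hybrids otherwise. NULL means
#'   identity.
#' @param spatial \code{"none"} (iid residual) or \code{"ar1"}.
#' @param inner_maxit,outer_maxit iteration caps for the AR1 profile search
#'   (ignored for \code{spatial = "none"}).
#' @param ... passed to \code{\link{reml_mixed}}.
#' @return a \code{trial_fit}: the underlying \code{reml_fit} plus
#'   \code{effects} (data.frame of genetic BLUPs with PEV and reliability)
#'   and \code{h2} (mean reliability of the genetic/additive term).
#' @export
fit_trial <- function(pheno, genetic = c("additive", "hybrid"), rel = NULL,
                      spatial = c("none", "ar1"), inner_maxit = 60,
                      outer_maxit = 40, ...) {
  genetic <- match.arg(genetic)
  spatial <- match.arg(spatial)
  need <- c("row", "col", "block", "entry", "is_check", "yield")
  stop_if(!all(need %in% names(pheno)), "pheno lacks columns: %s",
          paste(setdiff(need, names(pheno)), collapse = ", "))
  y <- pheno$yield
  n <- nrow(pheno)

  checks <- sort(unique(pheno$entry[pheno$is_check]))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(checks) > 0) {
    Xc <- indicator(ifelse(pheno$is_check, pheno$entry, "_hybrid"),
                    levels = c("_hybrid", checks))[, -1, drop = FALSE]
    X <- cbind(X, Xc)
  }

  Zlist <- list(row = indicator(pheno$row), col = indicator(pheno$col),
                block = indicator(pheno$block))
  Klist <- list(NULL, NULL, NULL)
  hyb <- pheno$entry[!pheno$is_check]
  if (genetic == "hybrid") {
    levs <- if (!is.null(rel)) rownames(rel) else sort(unique(hyb))
    Zg <- indicator(ifelse(pheno$is_check, NA, pheno$entry), levels = levs)
    Zg[is.na(Zg)] <- 0
    Zlist$genetic <- Zg
    Klist <- c(Klist, list(rel))
  } else {
    crosses <- unique(pheno[!pheno$is_check, c("entry", "male", "female")])
    names(crosses)[1] <- "hybrid"
    parents <- if (!is.null(rel)) rownames(rel)
               else sort(unique(c(crosses$male, crosses$female)))
    Tm <- build_hybrid_additive_design(crosses, parents)
    Zh <- indicator(ifelse(pheno$is_check, NA, pheno$entry),
                    levels = rownames(Tm))
    Zh[is.na(Zh)] <- 0
    Zlist$additive <- Zh %*% Tm
    Zlist$nonadditive <- Zh
    Klist <- c(Klist, list(rel), list(NULL))
  }

  fit <- if (spatial == "none") reml_mixed(y, X, Zlist, Klist, ...)
         else reml_ar1(y, X, Zlist, Klist, row = pheno$row, col = pheno$col,
                       inner_maxit = inner_maxit, outer_maxit = outer_maxit)

  gterm <- if (genetic == "hybrid") "genetic" else "additive"
  eff <- data.frame(term = gterm, level = names(fit$u[[gterm]]),
                    blup = unname(fit$u[[gterm]]),
                    pev = unname(fit$pev[[gterm]]),
                    reliability = unname(fit$reliability[[gterm]]),
                    stringsAsFactors = FALSE)
  if (genetic == "additive")
    eff$observed_at_site <- unname(colSums(Zlist$additive) > 0)[
      match(eff$level, colnames(Zlist$additive))]
  fit$effects <- eff
  fit$h2 <- mean(eff$reliability, na.rm = TRUE)
  fit$genetic <- genetic
  fit$spatial <- spatial
  class(fit) <- c("trial_fit", class(fit))
  fit
}

#' Compare iid and AR1 x AR1 residual structures for one trial
#'
#' Fits both residual variants of the same mean/random model and selects by
#' AIC on the REML log-likelihood (the fixed part is identical, making the
#' comparison valid). Both fits are returned regardless of the winner. A
#' layout with a single row or column falls back to AR1 in the remaining
#' direction only (the degenerate direction's correlation is pinned at 0).
#'
#' @param pheno plot table as in \code{\link{fit_trial}}.
#' @param genetic,rel passed to \code{\link{fit_trial}}.
#' @param ... further arguments for the fitters.
#' @return list with \code{selected} ("iid" or "ar1"), \code{aic} (named),
#'   \code{fit_iid}, \code{fit_ar1}.
#' @export
compare_spatial <- function(pheno, genetic = "additive", rel = NULL,
                            inner_maxit = 60, outer_maxit = 40, ...) {
  fit_iid <- fit_trial(pheno, genetic = genetic, rel = rel, spatial = "none", ...)
  fit_ar1 <- fit_trial(pheno, genetic = genetic, rel = rel, spatial = "ar1",
                       inner_maxit = inner_maxit, outer_maxit = outer_maxit, ...)
  aic <- c(iid = -2 * fit_iid$loglik + 2 * fit_iid$n_params,
           ar1 = -2 * fit_ar1$loglik + 2 * fit_ar1$n_params)
  list(selected = names(aic)[which.min(aic)], aic = aic,
       fit_iid = fit_iid, fit_ar1 = fit_ar1)
}
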