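#' Shukla's stability variance
#'
#' Partitions genotype-by-environment interaction into per-genotype
#' variances. With interaction residuals
#' w_ij = x_ij - xbar_i. - xbar_.j + xbar_.. over G genotypes and E
#' environments, genotype i's stability variance is
#' \deqn{\sigma^2_i = \frac{G}{(G-2)(E-1)} \sum_j w_{ij}^2 -
#'       \frac{\sum_i \sum_j w_{ij}^2}{(G-1)(G-2)(E-1)}}
#' The estimator is unbiased and can be negative; negative values are kept
#' as-is with a truncated-at-zero companion column.
#'
#' @param effects genotypes x environments matrix of effects (e.g. per-site
#'   additive BLUPs of parents).
#' @param complete require a complete table (default TRUE); with FALSE,
#'   missing cells are EM-style filled at row+column expectations with a
#'   warning.
#' @return data.frame: genotype, mean (row mean), sigma2 (Shukla variance),
#'   sigma2_trunc (floored at 0), sqrt_stability.
#' @export
shukla_variance <- function(effects, complete = TRUE) {
  X <- as.matrix(effects)
  G <- nrow(X); E <- ncol(X)
  stop_if(G < 3, "need at least 3 genotypes (G - 2 in the denominator)")
  stop_if(E < 2, "need at least 2 environments")
  if (anyNA(X)) {
    stop_if(complete, "missing cells in the effects table (set complete = FALSE to mean-fill)")
    warning("mean-filling missing cells at row + column expectations")
    miss <- is.na(X)
    X[miss] <- mean(X, na.rm = TRUE)
    for (rep in 1:100) {
      fill <- outer(rowMeans(X), colMeans(X), "+") - mean(X)
      delta <- max(abs(X[miss] - fill[miss]))
      X[miss] <- fill[miss]
      if (delta < 1e-10) break
    }
  }
  W <- X - rowMeans(X)[row(X)] - colMeans(X)[col(X)] + mean(X)
  ssq_i <- rowSums(W^2)
  ssq <- sum(ssq_i)
  sigma2 <- G * ssq_i / ((G - 2) * (E - 1)) - ssq / ((G - 1) * (G - 2) * (E - 1))
  data.frame(genotype = if (is.null(rownames(X))) seq_len(G) else rownames(X),
             mean = rowMeans(X),
             sigma2 = sigma2,
             sigma2_trunc = pmax(sigma2, 0),
             sqrt_stability = sqrt(pmax(sigma2, 0)),
             stringsAsFactors = FALSE)
}

#' Mean-versus-stability quadrant classification
#'
#' Classifies each parent by its mean additive effect against the square
#' root of its Shukla stability variance. "Stable positive" parents — the
#' candidate seeds of a heterotic pool — combine a mean above
#' \code{mean_threshold} with a stability value below
#' \code{stability_threshold} (low variance = stable). The axis orientation
#' is recorded in the output attributes.
#'
#' @param table output of \code{\link{shukla_variance}} (optionally with a
#'   \code{subgroup} column added).
#' @param mean_threshold vertical split (default 0).
#' @param stability_threshold horizontal split; default the panel median of
#'   \code{sqrt_stability}.
#' @return the table with a \code{quadrant} factor added; attributes
#'   \code{mean_threshold}, \code{stability_threshold},
#'   \code{orientation}.
#' @export
quadrant_classify <- function(table, mean_threshold = 0,
                              stability_threshold = NULL) {
  stop_if(nrow(table) == 0, "empty stability table")
  stopifnot(all(c("mean", "sqrt_stability") %in% names(table)))
  if (is.null(stability_threshold))
    stability_threshold <- stats::median(table$sqrt_stability)
  pos <- table$mean > mean_threshold
  stable <- table$sqrt_stability < stability_threshold
  table$quadrant <- factor(ifelse(pos & stable, "stable-positive",
                           ifelse(pos & !stable, "unstable-positive",
                           ifelse(!pos & stable, "stable-negative",
                                  "unstable-negative"))),
                           levels = c("stable-positive", "unstable-positive",
                                      "stable-negative", "unstable-negative"))
  attr(table, "mean_threshold") <- mean_threshold
  attr(table, "stability_threshold") <- stability_threshold
  attr(table, "orientation") <-
    "stable-positive = mean above threshold AND sqrt stability below threshold"
  table
}
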