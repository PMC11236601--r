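#' @keywords internal
"_PACKAGE"

## Internal validation helpers ------------------------------------------------

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          "'%s' must be a single finite number", name)
  lo_bad <- if (open_lower) x <= lower else x < lower
  hi_bad <- if (open_upper) x >= upper else x > upper
  stop_if(lo_bad || hi_bad, "'%s' = %g is outside the allowed range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
            x != round(x) || x < min,
          "'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

#' Derive a reproducible sub-seed for a named component
#'
#' All randomness in the package flows from one user-supplied seed; each
#' component draws from its own stream derived deterministically from the
#' master seed and a label, so adding draws to one component does not
#' perturb another.
#'
#' @param seed master integer seed.
#' @param label character label of the component stream.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stop_if(!is.numeric(seed) || length(seed) != 1L, "'seed' must be a single integer")
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435.0) %% 1e9
  as.integer((abs(seed) * 31 + h) %% 2147483629)
}

## Symmetric PSD check with tolerance
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}
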