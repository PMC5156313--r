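#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector with `estimate`, `lower`, `upper`.
#' @examples
#' wilson_ci(5, 10)
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p,
    lower = max(0, centre - half),
    upper = min(1, centre + half))
}

# internal: check a scalar probability
check_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      x > 1 || (!allow_one && x == 1)) {
    stop(sprintf("`%s` must be a probability in [0,%s], got %s",
                 name, if (allow_one) "1" else "1)", format(x)), call. = FALSE)
  }
  invisible(x)
}

# internal: positive scalar
check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s number, got %s", name,
                 if (strict) "positive" else "non-negative", format(x)),
         call. = FALSE)
  }
  invisible(x)
}
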