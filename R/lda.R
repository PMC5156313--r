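#' Call engraftment from bioluminescence fluxes
#'
#' A mouse is scored engrafted iff its photon flux reaches the imaging
#' detection threshold (default `5e5` photons/s); the comparison is
#' inclusive, so a flux exactly at the threshold is a positive call.
#'
#' @param photon_fluxes Non-negative per-mouse fluxes (photons/s).
#' @param threshold Detection threshold.
#' @return Logical vector of engraftment calls.
#' @export
call_engraftment <- function(photon_fluxes, threshold = 5e5) {
  if (any(photon_fluxes < 0)) stop("negative photon flux", call. = FALSE)
  check_pos(threshold, "threshold")
  photon_fluxes >= threshold
}

# internal: validate an LDA table
check_lda_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("dose", "n_mice", "n_engrafted") %in% names(table)))
  if (nrow(table) < 1) stop("empty LDA table", call. = FALSE)
  if (any(table$dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(table$n_engrafted < 0 | table$n_engrafted > table$n_mice)) {
    stop("n_engrafted must lie in [0, n_mice]", call. = FALSE)
  }
  table
}

# internal: binomial log-likelihood of frequency f for an LDA table
lda_loglik <- function(f, table) {
  p <- 1 - (1 - f)^table$dose
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  # exact 0/1 handled by clamping; k = 0 or k = n rows stay finite
  sum(stats::dbinom(table$n_engrafted, table$n_mice, p, log = TRUE))
}

#' Single-hit Poisson limiting-dilution estimate of initiating-cell frequency
#'
#' Under the single-hit model a transplant of `d` cells engrafts iff it
#' contains at least one initiating cell, so
#' `P(engraft | d) = 1 - (1 - f)^d`. The frequency `f` is estimated by
#' maximizing the binomial log-likelihood over `log f`; the 95% confidence
#' interval inverts the profile likelihood at the chi-squared(1) cutoff
#' (drop of 1.92 from the maximum). All-negative tables give `f = 0` with a
#' one-sided upper bound; all-positive tables give `f = 1` with a one-sided
#' lower bound. Goodness of fit is a likelihood-ratio test against the
#' saturated per-dose binomial model.
#'
#' @param table Data frame with columns `dose`, `n_mice`, `n_engrafted`.
#' @param ci_method `"profile"` (default) or `"wald"` (normal interval on
#'   `log f`).
#' @param conf Confidence level (the profile cutoff is
#'   `qchisq(conf, 1) / 2`).
#' @return A list of class `"lda_result"`: `fhat`, `ci` (`lower`, `upper`),
#'   `one_in` (frequencies as "1/n" strings), `loglik`, `gof_p`, `flags`,
#'   `table`.
#' @examples
#' fit_single_hit(data.frame(dose = 10, n_mice = 10, n_engrafted = 5))
#' @export
fit_single_hit <- function(table, ci_method = c("profile", "wald"),
                           conf = 0.95) {
  ci_method <- match.arg(ci_method)
  table <- check_lda_table(table)
  cutoff <- stats::qchisq(conf, 1) / 2
  lo_logf <- log(1e-9)
  flags <- character()
  ll <- function(logf) lda_loglik(exp(logf), table)

  all_neg <- all(table$n_engrafted == 0)
  all_pos <- all(table$n_engrafted == table$n_mice)
  if (all_neg) {
    fhat <- 0
    llmax <- 0
    target <- llmax - cutoff
    upper <- exp(stats::uniroot(function(x) ll(x) - target,
                                c(lo_logf, 0), tol = 1e-10)$root)
    ci <- c(lower = 0, upper = upper)
    flags <- c(flags, "all_negative", "one_sided_upper")
  } else if (all_pos) {
    fhat <- 1
    llmax <- 0
    target <- llmax - cutoff
    lower <- exp(stats::uniroot(function(x) ll(x) - target,
                                c(lo_logf, 0), tol = 1e-10)$root)
    ci <- c(lower = lower, upper = 1)
    flags <- c(flags, "all_positive", "one_sided_lower")
  } else {
    opt <- stats::optimize(ll, interval = c(lo_logf, 0), maximum = TRUE,
                           tol = 1e-10)
    fhat <- exp(opt$maximum)
    llmax <- opt$objective
    if (ci_method == "profile") {
      target <- llmax - cutoff
      lower <- tryCatch(
        exp(stats::uniroot(function(x) ll(x) - target,
                           c(lo_logf, opt$maximum), tol = 1e-10)$root),
        error = function(e) {
          flags <<- c(flags, "lower_at_boundary")
          0
        })
      upper <- if (ll(0) - target > 0) {
        flags <- c(flags, "upper_at_boundary")
        1
      } else {
        exp(stats::uniroot(function(x) ll(x) - target,
                           c(opt$maximum, 0), tol = 1e-10)$root)
      }
      ci <- c(lower = lower, upper = upper)
    } else {
      h <- 1e-4
      d2 <- (ll(opt$maximum + h) - 2 * llmax + ll(opt$maximum - h)) / h^2
      se_logf <- 1 / sqrt(-d2)
      z <- stats::qnorm(1 - (1 - conf) / 2)
      ci <- c(lower = exp(opt$maximum - z * se_logf),
              upper = min(1, exp(opt$maximum + z * se_logf)))
    }
  }
  # goodness of fit vs saturated per-dose model
  p_sat <- table$n_engrafted / table$n_mice
  ll_sat <- sum(stats::dbinom(table$n_engrafted, table$n_mice,
                              p_sat, log = TRUE))
  df <- nrow(table) - 1
  gof_p <- if (df > 0) {
    stats::pchisq(2 * (ll_sat - llmax), df, lower.tail = FALSE)
  } else NA_real_
  one_in <- function(f) {
    if (f <= 0) "0" else paste0("1/", round(1 / f))
  }
  structure(list(
    fhat = fhat,
    ci = ci,
    one_in = c(estimate = one_in(fhat), lower = one_in(ci[["upper"]]),
               upper = one_in(ci[["lower"]])),
    loglik = llmax,
    gof_p = gof_p,
    flags = flags,
    ci_method = ci_method,
    table = table
  ), class = "lda_result")
}

#' Likelihood-ratio comparison of two initiating-cell frequencies
#'
#' Tests the null that two limiting-dilution experiments share a common
#' initiating-cell frequency: twice the gain in log-likelihood of separate
#' fits over the pooled fit, referred to chi-squared with one degree of
#' freedom.
#'
#' @param a,b LDA tables (see [fit_single_hit()]).
#' @return A list: `statistic`, `p_value`, `fit_a`, `fit_b`, `fit_pooled`.
#' @export
compare_frequencies <- function(a, b) {
  a <- check_lda_table(a)
  b <- check_lda_table(b)
  fit_a <- fit_single_hit(a)
  fit_b <- fit_single_hit(b)
  fit_pool <- fit_single_hit(rbind(a, b))
  stat <- max(0, 2 * (fit_a$loglik + fit_b$loglik - fit_pool$loglik))
  if (any(c(fit_a$fhat, fit_b$fhat) %in% c(0, 1))) {
    warning("a frequency estimate lies on the boundary; the chi-squared ",
            "reference for the likelihood ratio is approximate",
            call. = FALSE)
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       fit_a = fit_a, fit_b = fit_b, fit_pooled = fit_pool)
}
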