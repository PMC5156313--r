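#' Homing efficiency from day-3 recovery
#'
#' Point estimate and Wilson confidence interval of the fraction of injected
#' cells recovered from the bone marrow shortly after intravenous injection.
#'
#' @param n_injected Number of cells injected (> 0).
#' @param n_recovered Number of cells recovered at day 3.
#' @param conf Confidence level.
#' @return Named numeric vector `estimate`, `lower`, `upper`.
#' @export
homing_efficiency <- function(n_injected, n_recovered, conf = 0.95) {
  check_pos(n_injected, "n_injected")
  if (n_recovered < 0) stop("`n_recovered` must be >= 0", call. = FALSE)
  if (n_recovered > n_injected) {
    stop("recovered more cells than injected (", n_recovered, " > ",
         n_injected, "); check the inputs", call. = FALSE)
  }
  wilson_ci(n_recovered, n_injected, conf)
}

# internal: validate a burden series; left-censor zeros at half the
# detection limit
prepare_series <- function(series, min_points, detection_limit = NULL) {
  stopifnot(is.data.frame(series), all(c("day", "burden") %in% names(series)))
  if (nrow(series) < min_points) {
    stop("insufficient data: need at least ", min_points, " time points",
         call. = FALSE)
  }
  if (any(series$burden < 0)) stop("negative burdens", call. = FALSE)
  if (any(series$burden == 0)) {
    pos <- series$burden[series$burden > 0]
    if (is.null(detection_limit)) detection_limit <- min(pos)
    warning("zero burdens left-censored at half the detection limit (",
            format(detection_limit / 2), ")", call. = FALSE)
    series$burden[series$burden == 0] <- detection_limit / 2
  }
  series[order(series$day), , drop = FALSE]
}

# internal: Gaussian log-likelihood of log-scale residuals (sigma at MLE),
# and AICc/BIC for k parameters (sigma counted)
loglik_lognormal <- function(resid_log, k_model) {
  n <- length(resid_log)
  sigma2 <- mean(resid_log^2)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- k_model + 1
  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  bic <- -2 * ll + k * log(n)
  list(loglik = ll, k = k, aicc = aicc, bic = bic,
       rmse_log = sqrt(sigma2))
}

# internal: key identifying the data a fit was computed on
series_key <- function(series) {
  paste0(nrow(series), ":", format(sum(series$day), digits = 12), ":",
         format(sum(log(series$burden)), digits = 12))
}

new_growth_fit <- function(model, coef, se, ll, n, converged = TRUE,
                           flags = character(), key) {
  structure(list(model = model, coef = coef, se = se,
                 loglik = ll$loglik, k = ll$k, aicc = ll$aicc, bic = ll$bic,
                 rmse_log = ll$rmse_log, n = n, converged = converged,
                 flags = flags, series_key = key),
            class = "growth_fit")
}

#' Fit an exponential growth model to a burden time series
#'
#' Least squares of log burden against day, the maximum-likelihood fit under
#' multiplicative lognormal noise: `N(t) = N0 * exp(r t)`.
#'
#' @param series Data frame with columns `day` and `burden` (> 0; zeros are
#'   left-censored at half the detection limit with a warning).
#' @param detection_limit Optional detection limit used for censoring zeros;
#'   defaults to the smallest positive burden.
#' @return A `"growth_fit"` with `coef` = `c(N0, r)`, standard errors,
#'   log-likelihood and AICc/BIC on the log scale.
#' @export
fit_exponential <- function(series, detection_limit = NULL) {
  series <- prepare_series(series, 3, detection_limit)
  fit <- stats::lm(log(burden) ~ day, data = series)
  cf <- stats::coef(fit)
  se_raw <- sqrt(diag(stats::vcov(fit)))
  N0 <- exp(cf[[1]])
  coef <- c(N0 = N0, r = cf[[2]])
  se <- c(N0 = N0 * se_raw[[1]], r = se_raw[[2]])
  ll <- loglik_lognormal(stats::residuals(fit), k_model = 2)
  new_growth_fit("exponential", coef, se, ll, nrow(series),
                 key = series_key(series))
}

#' Fit a logistic growth model to a burden time series
#'
#' Nonlinear least squares of log burden against the log of
#' `N(t) = K / (1 + (K/N0 - 1) exp(-r t))`, parameterized in
#' `(log N0, r, log K)` with a multi-start grid: `N0` from the first
#' observation, `r` from the early log-slope, and `K` at 2, 10 and 100 times
#' the maximum observed burden. Non-convergence of every start is an error;
#' a fit whose carrying capacity is not identified from the data (no visible
#' saturation) carries the flag `"K_unidentifiable"`.
#'
#' @param series Data frame with `day` and `burden`.
#' @param detection_limit As in [fit_exponential()].
#' @param fix_K Optionally fix the carrying capacity and fit only
#'   `(N0, r)` — useful for testing the exponential limit `K -> Inf`.
#' @return A `"growth_fit"` with `coef` = `c(N0, r, K)`.
#' @export
fit_logistic <- function(series, detection_limit = NULL, fix_K = NULL) {
  series <- prepare_series(series, 4, detection_limit)
  key <- series_key(series)
  day <- series$day
  logb <- log(series$burden)
  n_early <- min(4, nrow(series))
  r0 <- stats::coef(stats::lm(logb[1:n_early] ~ day[1:n_early]))[[2]]
  r0 <- max(r0, 0.01)
  logN0_0 <- logb[1] - r0 * day[1]
  log_mu <- function(logN0, r, logK, t) {
    # log K - log(1 + (K/N0 - 1) e^{-rt}), stable via log1p
    logK - log1p(pmax(exp(logK - logN0) - 1, 0) * exp(-r * t))
  }
  if (!is.null(fix_K)) {
    fit <- minpack.lm::nlsLM(
      logb ~ log_mu(logN0, r, log(fix_K), day),
      start = list(logN0 = logN0_0, r = r0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    se_raw <- sqrt(diag(stats::vcov(fit)))
    N0 <- exp(cf[["logN0"]])
    coef <- c(N0 = N0, r = cf[["r"]], K = fix_K)
    se <- c(N0 = N0 * se_raw[["logN0"]], r = se_raw[["r"]], K = NA)
    ll <- loglik_lognormal(stats::residuals(fit), k_model = 2)
    return(new_growth_fit("logistic", coef, se, ll, nrow(series),
                          flags = "K_fixed", key = key))
  }
  starts <- lapply(c(2, 10, 100), function(mult) {
    list(logN0 = logN0_0, r = r0, logK = log(mult * max(series$burden)))
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        logb ~ log_mu(logN0, r, logK, day),
        start = st,
        lower = c(-Inf, 1e-6, log(max(series$burden))),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # no start converged: the likelihood is flat in K (no saturation in the
    # data) — fall back to the exponential limit with K at the boundary
    K_bound <- 1e6 * max(series$burden)
    fit <- minpack.lm::nlsLM(
      logb ~ log_mu(logN0, r, log(K_bound), day),
      start = list(logN0 = logN0_0, r = r0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    se_raw <- sqrt(diag(stats::vcov(fit)))
    N0 <- exp(cf[["logN0"]])
    coef <- c(N0 = N0, r = cf[["r"]], K = K_bound)
    se <- c(N0 = N0 * se_raw[["logN0"]], r = se_raw[["r"]], K = Inf)
    ll <- loglik_lognormal(stats::residuals(fit), k_model = 3)
    return(new_growth_fit("logistic", coef, se, ll, nrow(series),
                          converged = FALSE,
                          flags = "K_unidentifiable", key = key))
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  se_raw <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) rep(NA_real_, 3))
  names(se_raw) <- names(cf)
  N0 <- exp(cf[["logN0"]])
  K <- exp(cf[["logK"]])
  coef <- c(N0 = N0, r = cf[["r"]], K = K)
  se <- c(N0 = N0 * se_raw[["logN0"]], r = se_raw[["r"]],
          K = K * se_raw[["logK"]])
  flags <- character()
  if (!is.finite(se_raw[["logK"]]) || se_raw[["logK"]] > 2 ||
      K > 1e3 * max(series$burden)) {
    flags <- c(flags, "K_unidentifiable")
  }
  ll <- loglik_lognormal(stats::residuals(fit), k_model = 3)
  new_growth_fit("logistic", coef, se, ll, nrow(series),
                 converged = TRUE, flags = flags, key = key)
}

#' Select a growth model by information criterion
#'
#' Compares fits of different growth models on the same burden series by
#' AICc (default) or BIC. The smallest criterion wins; if the runner-up is
#' within `equivocal_delta` (default 2) the selection is reported as
#' equivocal rather than forced.
#'
#' @param fits List of `"growth_fit"` objects on the identical series.
#' @param criterion `"aicc"` or `"bic"`.
#' @param equivocal_delta Delta below which models are considered tied.
#' @return A list: `choice` (winning model name, or `"equivocal"`),
#'   `best` (winning model name regardless of ties), `equivocal` (logical),
#'   `table` (data frame `model`, `loglik`, `k`, `criterion`, `delta`).
#' @export
select_model <- function(fits, criterion = c("aicc", "bic"),
                         equivocal_delta = 2) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "growth_fit")))
  keys <- vapply(fits, `[[`, character(1), "series_key")
  if (length(unique(keys)) != 1) {
    stop("fits were computed on different series; model selection requires ",
         "the identical data", call. = FALSE)
  }
  crit <- vapply(fits, `[[`, numeric(1), criterion)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    criterion = crit,
    delta = crit - min(crit)
  )
  tab <- tab[order(tab$criterion), , drop = FALSE]
  equivocal <- nrow(tab) >= 2 && tab$delta[2] < equivocal_delta
  list(choice = if (equivocal) "equivocal" else tab$model[1],
       best = tab$model[1],
       equivocal = equivocal,
       table = tab)
}
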