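#' Per-class survival fractions after treatment
#'
#' For each gate class the survival fraction is the treated cell count over
#' the control cell count, with a confidence interval from the conditional
#' binomial treatment of a ratio of two Poisson counts. Classes with a zero
#' control count are excluded with a warning.
#'
#' @param control,treated Named integer vectors of per-class counts (e.g.
#'   from gating), or `"gated_sample"` objects.
#' @param conf Confidence level.
#' @return Data frame: `class`, `control`, `treated`, `fraction`, `lower`,
#'   `upper`.
#' @export
survival_fractions <- function(control, treated, conf = 0.95) {
  if (inherits(control, "gated_sample")) control <- gated_counts(control)
  if (inherits(treated, "gated_sample")) treated <- gated_counts(treated)
  stopifnot(!is.null(names(control)), !is.null(names(treated)))
  classes <- intersect(names(control), names(treated))
  drop <- classes[control[classes] == 0]
  if (length(drop)) {
    warning("classes with zero control count excluded: ",
            paste(drop, collapse = ", "), call. = FALSE)
    classes <- setdiff(classes, drop)
  }
  rows <- lapply(classes, function(cl) {
    c_ctrl <- control[[cl]]
    c_trt <- treated[[cl]]
    # ratio of two Poisson means: condition on the total
    bt <- stats::binom.test(c_trt, c_trt + c_ctrl, conf.level = conf)
    ci_p <- bt$conf.int
    data.frame(class = cl, control = c_ctrl, treated = c_trt,
               fraction = c_trt / c_ctrl,
               lower = ci_p[1] / (1 - ci_p[1]),
               upper = if (ci_p[2] >= 1) Inf else ci_p[2] / (1 - ci_p[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative drug effect on LRC, scaled to non-LRC = 100%
#'
#' The elimination fraction of a class is one minus its survival fraction.
#' The relative drug effect expresses the drug's elimination of LRC as a
#' percentage of its elimination of non-LRC: equal eliminations give 100,
#' untouched LRC give 0, and a value of 1 corresponds to a hundredfold less
#' efficient elimination of LRC.
#'
#' @param lrc_survival Survival fraction of LRC.
#' @param nonlrc_survival Survival fraction of non-LRC (elimination must be
#'   positive).
#' @return Relative drug effect in percent.
#' @examples
#' relative_drug_effect(0.9, 0.1) # LRC barely touched: ~11%
#' @export
relative_drug_effect <- function(lrc_survival, nonlrc_survival) {
  stopifnot(lrc_survival >= 0, nonlrc_survival >= 0)
  elim_lrc <- 1 - lrc_survival
  elim_non <- 1 - nonlrc_survival
  if (elim_non <= 0) {
    stop("non-LRC elimination is zero: relative drug effect undefined",
         call. = FALSE)
  }
  100 * elim_lrc / elim_non
}

#' Call minimal residual disease from marrow blast percentage
#'
#' MRD is a burden strictly below the threshold (default < 1% human cells
#' in bone marrow). Burdens below the molecular threshold (default 0.1%)
#' are additionally tiered as molecular-remission-like.
#'
#' @param pct_blasts Percentage of blasts in bone marrow, in `[0, 100]`
#'   (vectorized).
#' @param threshold MRD threshold in percent (strict `<`).
#' @param molecular_threshold Molecular-remission-like tier threshold.
#' @return Data frame: `pct_blasts`, `mrd` (logical), `tier` (factor
#'   `overt` / `mrd` / `molecular`).
#' @export
call_mrd <- function(pct_blasts, threshold = 1, molecular_threshold = 0.1) {
  if (any(pct_blasts < 0 | pct_blasts > 100)) {
    stop("`pct_blasts` must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(molecular_threshold < threshold)
  mrd <- pct_blasts < threshold
  tier <- ifelse(pct_blasts < molecular_threshold, "molecular",
                 ifelse(mrd, "mrd", "overt"))
  data.frame(pct_blasts = pct_blasts, mrd = mrd,
             tier = factor(tier, levels = c("overt", "mrd", "molecular")))
}

#' LRC enrichment fold between two time points
#'
#' Fold-change of the LRC proportion after versus before treatment, with a
#' delta-method confidence interval on the log fold from the two binomial
#' fractions when sample sizes are supplied.
#'
#' @param pre_fraction LRC fraction before treatment (> 0).
#' @param post_fraction LRC fraction after treatment.
#' @param pre_n,post_n Optional sample sizes behind the two fractions.
#' @param conf Confidence level.
#' @return Named vector `fold`, `lower`, `upper` (`lower`/`upper` are `NA`
#'   without sample sizes or when `post_fraction` is 0).
#' @export
lrc_enrichment <- function(pre_fraction, post_fraction, pre_n = NULL,
                           post_n = NULL, conf = 0.95) {
  if (pre_fraction <= 0) stop("`pre_fraction` must be > 0", call. = FALSE)
  stopifnot(post_fraction >= 0, pre_fraction <= 1, post_fraction <= 1)
  fold <- post_fraction / pre_fraction
  lower <- upper <- NA_real_
  if (!is.null(pre_n) && !is.null(post_n) && post_fraction > 0) {
    v <- (1 - pre_fraction) / (pre_fraction * pre_n) +
      (1 - post_fraction) / (post_fraction * post_n)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lower <- fold * exp(-z * sqrt(v))
    upper <- fold * exp(z * sqrt(v))
  }
  c(fold = fold, lower = lower, upper = upper)
}
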