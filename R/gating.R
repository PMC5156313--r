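#' Gate configuration for LRC classification
#'
#' Cells are classified from their label MFI relative to the day-3 reference:
#' label-retaining cells (LRC) have undergone at most `lrc_max_bisections`
#' label bisections, non-LRC at least `nonlrc_min_bisections`, everything in
#' between is "others". Defaults follow the standard gate: at most three
#' bisections for LRC, seven or more for non-LRC.
#'
#' @param lrc_max_bisections Maximum bisections for the LRC gate (inclusive).
#' @param nonlrc_min_bisections Minimum bisections for the non-LRC gate
#'   (inclusive).
#' @param reference_statistic Central statistic used to calibrate the day-3
#'   reference MFI: `"geometric_mean"` (default), `"median"` or `"mode"`.
#' @return A list of class `"gate_config"`.
#' @export
gate_config <- function(lrc_max_bisections = 3, nonlrc_min_bisections = 7,
                        reference_statistic = c("geometric_mean", "median",
                                                "mode")) {
  stopifnot(lrc_max_bisections >= 0,
            lrc_max_bisections < nonlrc_min_bisections)
  structure(list(
    lrc_max_bisections = lrc_max_bisections,
    nonlrc_min_bisections = nonlrc_min_bisections,
    reference_statistic = match.arg(reference_statistic)
  ), class = "gate_config")
}

#' Calibrate the day-3 reference MFI
#'
#' The reference MFI anchors division counting: it is the central label
#' intensity of cells measured at day 3 after injection, before the onset of
#' proliferation and after bleaching has ceased. The geometric mean is the
#' default because the readout noise is multiplicative; for a
#' median-preserving lognormal readout both the geometric mean and the
#' median are consistent for the true reference.
#'
#' @param day3_sample A flow-sample data frame with a `measured_mfi` column
#'   (see [measure_flow()]).
#' @param statistic `"geometric_mean"`, `"median"` or `"mode"` (the mode is
#'   the peak of a kernel density estimate on the log scale).
#' @return The reference MFI (scalar).
#' @export
calibrate_reference <- function(day3_sample,
                                statistic = c("geometric_mean", "median",
                                              "mode")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(day3_sample), "measured_mfi" %in% names(day3_sample))
  mfi <- day3_sample$measured_mfi
  if (length(mfi) == 0L) stop("empty day-3 sample", call. = FALSE)
  bad <- which(!is.finite(mfi) | mfi <= 0)
  if (length(bad)) {
    ids <- if ("cell_id" %in% names(day3_sample)) {
      day3_sample$cell_id[bad]
    } else bad
    stop("nonpositive MFI values for cells: ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  switch(statistic,
    geometric_mean = exp(mean(log(mfi))),
    median = stats::median(mfi),
    mode = {
      if (length(mfi) == 1L || stats::sd(log(mfi)) == 0) {
        return(exp(mean(log(mfi))))
      }
      dens <- stats::density(log(mfi))
      exp(dens$x[which.max(dens$y)])
    })
}

#' Count label bisections (divisions) from an MFI readout
#'
#' Each division halves the label, so the estimated division count is the
#' nearest integer to `log2(reference / mfi)`, clipped below at zero (cells
#' brighter than the reference are counted as undivided).
#'
#' @param mfi Measured MFI (vectorized, all > 0).
#' @param reference The calibrated day-3 reference MFI (> 0).
#' @return Integer vector of estimated division counts.
#' @examples
#' count_divisions(125, 1000) # 3 bisections
#' @export
count_divisions <- function(mfi, reference) {
  if (any(!is.finite(mfi) | mfi <= 0)) {
    stop("`mfi` must be positive", call. = FALSE)
  }
  check_pos(reference, "reference")
  as.integer(pmax(0, round(log2(reference / mfi))))
}

#' Classify cells into LRC / others / non-LRC
#'
#' Gating uses MFI thresholds placed at the half-bisection midpoints, so the
#' class boundaries and the rounded division counts never disagree by
#' construction: a cell is LRC iff its estimated division count is at most
#' `lrc_max_bisections` (equivalently
#' `mfi >= reference * 2^-(lrc_max_bisections + 0.5)`), and non-LRC iff the
#' count is at least `nonlrc_min_bisections`. A cell sitting exactly at a
#' whole-bisection intensity is classified boundary-inclusively (exactly
#' three bisections is LRC, exactly seven is non-LRC), and the midpoint
#' placement keeps classification unbiased under symmetric multiplicative
#' readout noise.
#'
#' @param sample A flow-sample data frame with `measured_mfi`.
#' @param reference Calibrated reference MFI.
#' @param gate A [gate_config()].
#' @return A list of class `"gated_sample"`: `cells` (the sample with
#'   `class` and `divisions_hat` columns), `counts` and `fractions` (named
#'   by class), `n`, `lrc_ci` (Wilson 95% CI on the LRC fraction),
#'   `reference` and `gate`.
#' @export
classify_cells <- function(sample, reference, gate = gate_config()) {
  stopifnot(is.data.frame(sample), "measured_mfi" %in% names(sample),
            inherits(gate, "gate_config"))
  check_pos(reference, "reference")
  if (nrow(sample) == 0L) {
    stop("empty sample: nothing to classify", call. = FALSE)
  }
  mfi <- sample$measured_mfi
  k_hat <- count_divisions(mfi, reference)
  cls <- ifelse(k_hat <= gate$lrc_max_bisections, "LRC",
                ifelse(k_hat >= gate$nonlrc_min_bisections, "nonLRC",
                       "others"))
  cls <- factor(cls, levels = c("LRC", "others", "nonLRC"))
  cells <- sample
  cells$class <- cls
  cells$divisions_hat <- k_hat
  counts <- table(cls)
  n <- nrow(sample)
  ci <- wilson_ci(sum(cls == "LRC"), n)
  structure(list(
    cells = cells,
    counts = as.integer(counts), # LRC, others, nonLRC
    fractions = as.numeric(counts) / n,
    n = n,
    lrc_ci = ci,
    reference = reference,
    gate = gate
  ), class = "gated_sample")
}

# internal: named class counts of a gated sample
gated_counts <- function(gs) {
  stopifnot(inherits(gs, "gated_sample"))
  stats::setNames(gs$counts, c("LRC", "others", "nonLRC"))
}

#' LRC kinetics over a time course
#'
#' Summarizes a series of gated samples (one per harvest day) into a tidy
#' table of LRC counts and fractions with Wilson confidence intervals,
#' ordered by day.
#'
#' @param samples A list of `"gated_sample"` objects.
#' @param days Numeric vector of harvest days, one per sample; duplicates
#'   are rejected.
#' @return A data frame: `day`, `n`, `lrc_count`, `lrc_fraction`,
#'   `lrc_lower`, `lrc_upper`.
#' @export
lrc_kinetics <- function(samples, days) {
  stopifnot(length(samples) >= 1, length(samples) == length(days))
  if (anyDuplicated(days)) stop("duplicate days in kinetics", call. = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    gs <- samples[[i]]
    stopifnot(inherits(gs, "gated_sample"))
    cnt <- gated_counts(gs)
    data.frame(day = days[i], n = gs$n, lrc_count = cnt[["LRC"]],
               lrc_fraction = gs$lrc_ci[["estimate"]],
               lrc_lower = gs$lrc_ci[["lower"]],
               lrc_upper = gs$lrc_ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  out[order(out$day), , drop = FALSE]
}
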