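#' Simulation configuration for label-diluting leukemic growth
#'
#' Bundles and validates all parameters of the stochastic engraftment
#' simulator: homing, logistic niche-limited growth, death, a rare reversible
#' dormant compartment, label (CFSE-like) dilution, flow-readout noise and the
#' bioluminescence readout.
#'
#' The defaults describe a typical xenograft experiment: \eqn{10^7} cells
#' injected intravenously of which a fraction of order \eqn{10^{-3}} homes to
#' the bone marrow, logistic expansion towards a niche carrying capacity over
#' a three-week horizon, and a dormant compartment seeded in about 1% of
#' engrafting cells.
#'
#' @param n_injected Number of cells injected intravenously.
#' @param homing_prob Probability that an injected cell lodges in the marrow.
#' @param r Per-day division rate of active cells (probability scale; the
#'   realized division probability is `r * (1 - N/K)` floored at 0).
#' @param K Niche carrying capacity in cells.
#' @param d Per-day death probability, in `[0, 1)`.
#' @param p_dormant_seed Probability that an engrafting cell starts dormant.
#' @param p_wake Per-day dormant-to-active switch probability.
#' @param p_sleep Per-day active-to-dormant switch probability.
#' @param dormant_div_rate Per-day division probability of dormant cells
#'   (much smaller than `r`; not density-limited).
#' @param M0 True initial post-bleaching label MFI (arbitrary units),
#'   defined at the day-3 reference time point.
#' @param cv_mfi Lognormal coefficient of variation of the measured MFI.
#' @param photons_per_cell Bioluminescence flux per cell (photons/s).
#' @param detection_threshold Flux above which engraftment is called
#'   (photons/s); default the imaging detection limit `5e5`.
#' @param n_days Simulation horizon in days.
#' @param hard_cap Abort if the population exceeds this many cells.
#' @param seed RNG seed, or `NULL` to leave the RNG state alone.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_injected = 1e4, homing_prob = 1, r = 0.5, K = 1e5)
#' @export
sim_config <- function(n_injected = 1e7,
                       homing_prob = 0.005,
                       r = 0.9,
                       K = 1e6,
                       d = 0.05,
                       p_dormant_seed = 0.01,
                       p_wake = 0.01,
                       p_sleep = 0.001,
                       dormant_div_rate = 0.01,
                       M0 = 1000,
                       cv_mfi = 0.2,
                       photons_per_cell = 100,
                       detection_threshold = 5e5,
                       n_days = 21,
                       hard_cap = 5e6,
                       seed = NULL) {
  check_pos(n_injected, "n_injected")
  check_prob(homing_prob, "homing_prob")
  if (homing_prob == 0) stop("`homing_prob` must be in (0, 1]", call. = FALSE)
  check_pos(r, "r", strict = FALSE)
  check_pos(K, "K")
  check_prob(d, "d", allow_one = FALSE)
  check_prob(p_dormant_seed, "p_dormant_seed")
  check_prob(p_wake, "p_wake")
  check_prob(p_sleep, "p_sleep")
  check_prob(dormant_div_rate, "dormant_div_rate")
  check_pos(M0, "M0")
  check_pos(cv_mfi, "cv_mfi", strict = FALSE)
  check_pos(photons_per_cell, "photons_per_cell")
  check_pos(detection_threshold, "detection_threshold")
  check_pos(n_days, "n_days", strict = FALSE)
  check_pos(hard_cap, "hard_cap")
  if (is.finite(K) && K < n_injected * homing_prob) {
    stop("carrying capacity `K` must be at least the expected homed cell ",
         "number `n_injected * homing_prob`", call. = FALSE)
  }
  structure(list(
    n_injected = n_injected, homing_prob = homing_prob, r = r, K = K, d = d,
    p_dormant_seed = p_dormant_seed, p_wake = p_wake, p_sleep = p_sleep,
    dormant_div_rate = dormant_div_rate, M0 = M0, cv_mfi = cv_mfi,
    photons_per_cell = photons_per_cell,
    detection_threshold = detection_threshold,
    n_days = n_days, hard_cap = hard_cap, seed = seed
  ), class = "sim_config")
}

#' Treatment plan: proliferation-dependent kill schedule
#'
#' A schedule of treatment days with separate kill probabilities for cells
#' that divided within the preceding day ("divided") and cells that did not
#' ("undivided"). Proliferation-dependent chemotherapy implies
#' `kill_prob_divided >= kill_prob_undivided`.
#'
#' @param days Integer vector of treatment days.
#' @param kill_prob_divided Kill probability for recently divided cells;
#'   recycled across days.
#' @param kill_prob_undivided Kill probability for undivided cells.
#' @return A data frame of class `"treatment_plan"` with one row per
#'   treatment day.
#' @export
treatment_plan <- function(days, kill_prob_divided, kill_prob_undivided) {
  stopifnot(length(days) >= 1, all(days >= 0), !anyDuplicated(days))
  n <- length(days)
  kd <- rep_len(kill_prob_divided, n)
  ku <- rep_len(kill_prob_undivided, n)
  for (i in seq_len(n)) {
    check_prob(kd[i], "kill_prob_divided")
    check_prob(ku[i], "kill_prob_undivided")
    if (kd[i] < ku[i]) {
      stop("kill_prob_divided must be >= kill_prob_undivided ",
           "(proliferation-dependent kill)", call. = FALSE)
    }
  }
  structure(data.frame(day = as.integer(days), kill_prob_divided = kd,
                       kill_prob_undivided = ku),
            class = c("treatment_plan", "data.frame"))
}

# internal: empty cohort frame
empty_cohort <- function() {
  data.frame(cell_id = integer(), divisions = integer(),
             compartment = character(), alive = logical(),
             divided_last_day = logical(), true_mfi = numeric())
}

# internal: one stochastic day for a live cohort (vectors), returns updated
# vectors. Division probability for active cells uses the day-start
# population size.
step_day <- function(divisions, dormant, cfg, n_start) {
  n <- length(divisions)
  if (n == 0L) return(list(divisions = divisions, dormant = dormant,
                           divided = logical(0)))
  # compartment switching (memoryless per-day probabilities)
  wake <- dormant & (stats::runif(n) < cfg$p_wake)
  sleep <- !dormant & (stats::runif(n) < cfg$p_sleep)
  dormant <- (dormant & !wake) | sleep
  # death
  die <- stats::runif(n) < cfg$d
  keep <- !die
  divisions <- divisions[keep]
  dormant <- dormant[keep]
  n <- length(divisions)
  if (n == 0L) return(list(divisions = divisions, dormant = dormant,
                           divided = logical(0)))
  # division: logistic slowdown for active cells, constant slow rate dormant
  p_active <- min(1, max(0, cfg$r * (1 - n_start / cfg$K)))
  p_dorm <- min(1, cfg$dormant_div_rate)
  p_div <- ifelse(dormant, p_dorm, p_active)
  divides <- stats::runif(n) < p_div
  # a dividing cell is replaced by two daughters, each with divisions + 1
  div_k <- divisions[divides] + 1L
  divisions <- c(divisions[!divides], div_k, div_k)
  dormant <- c(dormant[!divides], dormant[divides], dormant[divides])
  divided <- c(rep(FALSE, sum(!divides)), rep(TRUE, 2L * sum(divides)))
  list(divisions = divisions, dormant = dormant, divided = divided)
}

#' Simulate engraftment and in vivo growth of a labeled cohort
#'
#' Injected cells home independently to the marrow with `homing_prob`; the
#' homed cohort then evolves in discrete daily steps with binomial draws for
#' compartment switching, death and division. Active cells divide with
#' probability `r * (1 - N/K)` (floored at 0), producing logistic slowdown;
#' dormant cells divide with `dormant_div_rate`. Both daughters of a division
#' carry the parent's division count plus one, which halves the true label
#' MFI (`M0 * 2^-divisions`).
#'
#' If `plan` is given, on each treatment day cells that divided within the
#' preceding day are killed with `kill_prob_divided` and all others with
#' `kill_prob_undivided` (independent draws, applied after that day's growth
#' step).
#'
#' @param config A [sim_config()].
#' @param plan Optional [treatment_plan()].
#' @return A list of class `"engraftment_sim"` with elements
#'   \describe{
#'     \item{cells}{final cohort: `cell_id`, `divisions`, `compartment`,
#'       `alive`, `divided_last_day`, `true_mfi`.}
#'     \item{burden}{daily burden series: `day`, `n_cells`, `pct_blasts`
#'       (cells as a percentage of the niche capacity `K`), `flux`
#'       (photons/s), `n_dormant`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_engraftment(sim_config(n_injected = 2000, homing_prob = 1,
#'   r = 0.5, K = 1e5, d = 0, n_days = 5, seed = 1))
#' head(sim$burden)
#' @export
simulate_engraftment <- function(config, plan = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(plan)) stopifnot(inherits(plan, "treatment_plan"),
                                all(plan$day <= config$n_days))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_homed <- stats::rbinom(1, config$n_injected, config$homing_prob)
  divisions <- rep(0L, n_homed)
  dormant <- stats::runif(n_homed) < config$p_dormant_seed
  divided <- rep(FALSE, n_homed)
  days <- 0:config$n_days
  n_cells <- integer(length(days))
  n_dorm <- integer(length(days))
  n_cells[1] <- n_homed
  n_dorm[1] <- sum(dormant)
  for (t in seq_len(config$n_days)) {
    st <- step_day(divisions, dormant, config, length(divisions))
    divisions <- st$divisions
    dormant <- st$dormant
    divided <- st$divided
    if (length(divisions) > config$hard_cap) {
      stop(sprintf(
        "population (%d cells) exceeded hard_cap (%g) on day %d; raise K, ",
        length(divisions), config$hard_cap, t),
        "lower r, or raise hard_cap", call. = FALSE)
    }
    if (!is.null(plan) && t %in% plan$day) {
      row <- plan[match(t, plan$day), ]
      p_kill <- ifelse(divided, row$kill_prob_divided, row$kill_prob_undivided)
      keep <- stats::runif(length(divisions)) >= p_kill
      divisions <- divisions[keep]
      dormant <- dormant[keep]
      divided <- divided[keep]
    }
    n_cells[t + 1] <- length(divisions)
    n_dorm[t + 1] <- sum(dormant)
  }
  n <- length(divisions)
  cells <- data.frame(
    cell_id = seq_len(n),
    divisions = divisions,
    compartment = ifelse(dormant, "dormant", "active"),
    alive = rep(TRUE, n),
    divided_last_day = divided,
    true_mfi = config$M0 * 2^(-divisions)
  )
  burden <- data.frame(
    day = days,
    n_cells = n_cells,
    pct_blasts = 100 * n_cells / config$K,
    flux = config$photons_per_cell * n_cells,
    n_dormant = n_dorm
  )
  structure(list(cells = cells, burden = burden, config = config),
            class = "engraftment_sim")
}

#' Noisy flow-cytometry readout of a cohort's label intensity
#'
#' Measured MFI is the true MFI times a median-preserving lognormal factor:
#' `cv_mfi = 0` gives the exact readout and the geometric mean of the noisy
#' readout stays centred on the true value. Only alive cells are measured.
#'
#' @param cohort A cohort data frame (the `cells` element of an
#'   [simulate_engraftment()] result) or an `"engraftment_sim"` object.
#' @param cv_mfi Lognormal coefficient of variation of the readout.
#' @param seed Optional RNG seed.
#' @return A flow-sample data frame: `cell_id`, `measured_mfi`,
#'   `divisions_truth`, `compartment_truth`.
#' @export
measure_flow <- function(cohort, cv_mfi = 0, seed = NULL) {
  if (inherits(cohort, "engraftment_sim")) cohort <- cohort$cells
  stopifnot(is.data.frame(cohort))
  cohort <- cohort[cohort$alive, , drop = FALSE]
  if (nrow(cohort) == 0L) {
    stop("empty cohort: no alive cells to measure", call. = FALSE)
  }
  check_pos(cv_mfi, "cv_mfi", strict = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  if (cv_mfi == 0) {
    noise <- rep(1, n)
  } else {
    sigma <- sqrt(log(1 + cv_mfi^2))
    noise <- stats::rlnorm(n, meanlog = 0, sdlog = sigma)
  }
  data.frame(
    cell_id = cohort$cell_id,
    measured_mfi = cohort$true_mfi * noise,
    divisions_truth = cohort$divisions,
    compartment_truth = cohort$compartment
  )
}

#' Apply a proliferation-dependent treatment to a cohort
#'
#' For each scheduled treatment, cells flagged as having divided within the
#' preceding day are killed with `kill_prob_divided`, all others with
#' `kill_prob_undivided`; draws are independent across cells and treatments.
#' Killed cells are retained with `alive = FALSE`.
#'
#' @param cohort A cohort data frame with a `divided_last_day` column, or an
#'   `"engraftment_sim"` object.
#' @param plan A [treatment_plan()].
#' @param seed Optional RNG seed.
#' @return The cohort with `alive` updated.
#' @export
apply_treatment <- function(cohort, plan, seed = NULL) {
  if (inherits(cohort, "engraftment_sim")) cohort <- cohort$cells
  stopifnot(is.data.frame(cohort), inherits(plan, "treatment_plan"))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nrow(plan))) {
    at_risk <- which(cohort$alive)
    if (length(at_risk) == 0L) break
    p_kill <- ifelse(cohort$divided_last_day[at_risk],
                     plan$kill_prob_divided[i], plan$kill_prob_undivided[i])
    killed <- at_risk[stats::runif(length(at_risk)) < p_kill]
    cohort$alive[killed] <- FALSE
  }
  cohort
}

#' Simulate a limiting-dilution transplantation experiment
#'
#' Under the single-hit model each transplanted cell independently initiates
#' leukemia with probability `f_true`, so a mouse receiving `d` cells
#' engrafts with probability `1 - (1 - f_true)^d`.
#'
#' With `emit_flux = TRUE` a per-mouse bioluminescence readout is attached:
#' flux is `photons_per_cell` times the final burden, which for engrafted
#' mice is drawn lognormally around an outgrown leukemia (floored just above
#' the detection threshold) and for non-engrafted mice equals the injected
#' dose (so flux stays below threshold).
#'
#' @param f_true True initiating-cell frequency in `(0, 1]`, or 0.
#' @param doses Vector of cells-per-mouse doses.
#' @param mice_per_dose Number of mice per dose (recycled).
#' @param seed Optional RNG seed.
#' @param emit_flux If `TRUE` also return per-mouse photon fluxes.
#' @param photons_per_cell Flux per cell (photons/s).
#' @param detection_threshold Imaging detection threshold (photons/s).
#' @param burden_meanlog,burden_sdlog Lognormal parameters of the outgrown
#'   leukemia burden (cells) in engrafted mice.
#' @return A list with `table` (data frame `dose`, `n_mice`, `n_engrafted`)
#'   and, if requested, `mice` (data frame `dose`, `mouse`, `engrafted`,
#'   `flux`).
#' @export
simulate_lda <- function(f_true, doses, mice_per_dose, seed = NULL,
                         emit_flux = FALSE, photons_per_cell = 100,
                         detection_threshold = 5e5,
                         burden_meanlog = log(1e6), burden_sdlog = 0.5) {
  check_prob(f_true, "f_true")
  stopifnot(all(doses > 0))
  if (!is.null(seed)) set.seed(seed)
  n_mice <- rep_len(mice_per_dose, length(doses))
  p <- 1 - (1 - f_true)^doses
  mice <- NULL
  if (emit_flux) {
    engraft <- unlist(lapply(seq_along(doses), function(i) {
      stats::runif(n_mice[i]) < p[i]
    }))
    dose_col <- rep(doses, n_mice)
    burden <- ifelse(
      engraft,
      pmax(stats::rlnorm(length(engraft), burden_meanlog, burden_sdlog),
           1.01 * detection_threshold / photons_per_cell),
      dose_col)
    mice <- data.frame(
      dose = dose_col,
      mouse = sequence(n_mice),
      engrafted = engraft,
      flux = photons_per_cell * burden
    )
    n_eng <- tapply(engraft, factor(rep(seq_along(doses), n_mice)), sum)
    n_eng <- as.integer(n_eng)
  } else {
    n_eng <- stats::rbinom(length(doses), n_mice, p)
  }
  table <- data.frame(dose = doses, n_mice = n_mice, n_engrafted = n_eng)
  list(table = table, mice = mice)
}

#' Simulate a two-group expression count matrix with planted signal
#'
#' Negative-binomial counts for a dormant-versus-active comparison with a
#' planted set of differentially expressed genes. Per-gene baseline means
#' are drawn lognormally; planted genes get the specified log2 fold-change
#' in the dormant group. An optional global library-size factor below 1 for
#' the dormant group emulates the reduced RNA content of dormant cells.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_group Cells per group.
#' @param planted Data frame with columns `gene` (indices in
#'   `1:n_genes`) and `log2fc` (dormant over active), or `NULL` for a null
#'   simulation.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be positive.
#' @param lib_size_factor Global scaling of dormant-group expected counts.
#' @param base_meanlog,base_sdlog Lognormal parameters of per-gene baseline
#'   means.
#' @param seed Optional RNG seed.
#' @return A list: `counts` (genes x cells integer matrix, columns named by
#'   group), `groups` (factor `dormant`/`active` per column), `truth` (data
#'   frame `gene`, `log2fc`, `planted`).
#' @export
simulate_expression <- function(n_genes, n_cells_per_group, planted = NULL,
                                dispersion = 0.5, lib_size_factor = 1,
                                base_meanlog = log(20), base_sdlog = 1,
                                seed = NULL) {
  check_pos(n_genes, "n_genes")
  check_pos(n_cells_per_group, "n_cells_per_group")
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  check_pos(lib_size_factor, "lib_size_factor")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  lfc <- rep(0, n_genes)
  is_planted <- rep(FALSE, n_genes)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), all(c("gene", "log2fc") %in%
                                            names(planted)))
    idx <- planted$gene
    if (!all(idx %in% seq_len(n_genes))) {
      stop("planted genes must be indices within the gene universe",
           call. = FALSE)
    }
    if (any(!is.finite(planted$log2fc))) {
      stop("planted log2 fold-changes must be finite", call. = FALSE)
    }
    lfc[idx] <- planted$log2fc
    is_planted[idx] <- TRUE
  }
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  mu_dormant <- base * 2^lfc * lib_size_factor
  mu_active <- base
  size <- 1 / dispersion
  nc <- n_cells_per_group
  counts_d <- matrix(stats::rnbinom(n_genes * nc, mu = mu_dormant,
                                    size = size), nrow = n_genes)
  counts_a <- matrix(stats::rnbinom(n_genes * nc, mu = mu_active,
                                    size = size), nrow = n_genes)
  counts <- cbind(counts_d, counts_a)
  rownames(counts) <- genes
  colnames(counts) <- c(sprintf("dormant_%03d", seq_len(nc)),
                        sprintf("active_%03d", seq_len(nc)))
  groups <- factor(rep(c("dormant", "active"), each = nc),
                   levels = c("dormant", "active"))
  list(counts = counts, groups = groups,
       truth = data.frame(gene = genes, log2fc = lfc, planted = is_planted))
}

#' Re-transplant a cohort with a fresh label
#'
#' Models harvesting surviving cells, re-staining them (new reference MFI,
#' division counter reset to zero) and injecting them into a secondary
#' recipient. Compartment assignment is re-randomized by the niche on
#' re-engraftment (`p_dormant_seed`), so any selected subpopulation gives
#' rise to the same dormant fraction as a bulk transplant of equal size —
#' the reversibility property of dormancy.
#'
#' @param cohort A cohort data frame or `"engraftment_sim"`; only alive
#'   cells are re-injected.
#' @param config A [sim_config()] describing the secondary recipient;
#'   `n_injected` is replaced by the cohort size.
#' @return An `"engraftment_sim"` for the secondary recipient.
#' @export
retransplant <- function(cohort, config) {
  if (inherits(cohort, "engraftment_sim")) cohort <- cohort$cells
  stopifnot(is.data.frame(cohort), inherits(config, "sim_config"))
  n <- sum(cohort$alive)
  if (n == 0L) stop("no alive cells to re-transplant", call. = FALSE)
  cfg <- config
  cfg$n_injected <- n
  if (is.finite(cfg$K) && cfg$K < n * cfg$homing_prob) {
    stop("carrying capacity too small for re-transplant size", call. = FALSE)
  }
  simulate_engraftment(cfg)
}
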