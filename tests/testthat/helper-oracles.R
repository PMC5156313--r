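# Shared fixtures and independent oracles used across the suite.

# a simulator configuration with all dormancy dynamics switched off
quiet_config <- function(...) {
  defaults <- list(p_dormant_seed = 0, p_wake = 0, p_sleep = 0,
                   dormant_div_rate = 0, d = 0, cv_mfi = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# deterministic per-step discretization of logistic growth matching the
# simulator's daily map: N' = N * (1 - d) * (1 + min(1, max(0, r(1 - N/K))))
discrete_logistic <- function(N0, r, K, d, n_days) {
  out <- numeric(n_days + 1)
  out[1] <- N0
  for (t in seq_len(n_days)) {
    n <- out[t]
    p <- min(1, max(0, r * (1 - n / K)))
    out[t + 1] <- n * (1 - d) * (1 + p)
  }
  out
}

# closed-form continuous logistic solution
logistic_curve <- function(t, N0, r, K) K / (1 + (K / N0 - 1) * exp(-r * t))

# textbook Benjamini-Hochberg step-up, written directly from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact upper-tail overlap probability by direct enumeration over all
# possible overlap sizes (combinatorial sum, no phyper)
hyper_tail_enum <- function(q, n_a, n_b, universe) {
  ks <- max(0, n_a + n_b - universe):min(n_a, n_b)
  probs <- choose(n_a, ks) * choose(universe - n_a, n_b - ks) /
    choose(universe, n_b)
  sum(probs[ks >= q])
}

# brute-force grid-search MLE of the single-hit frequency over log f
grid_mle_f <- function(table, n_grid = 1e4) {
  grid <- exp(seq(log(1e-6), log(0.999), length.out = n_grid))
  ll <- vapply(grid, function(f) {
    p <- pmin(pmax(1 - (1 - f)^table$dose, 1e-300), 1 - 1e-16)
    sum(dbinom(table$n_engrafted, table$n_mice, p, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

# noiseless flow sample for cells at specified division counts
flow_at_divisions <- function(k, M0 = 1000) {
  data.frame(cell_id = seq_along(k),
             measured_mfi = M0 * 2^(-k),
             divisions_truth = k,
             compartment_truth = "active")
}

# a synthetic cohort data frame with a chosen divided-last-day split
make_cohort <- function(n, frac_divided, divisions = 1L) {
  n_div <- round(n * frac_divided)
  data.frame(
    cell_id = seq_len(n),
    divisions = rep(divisions, n),
    compartment = "active",
    alive = TRUE,
    divided_last_day = c(rep(TRUE, n_div), rep(FALSE, n - n_div)),
    true_mfi = 1000 * 2^(-divisions)
  )
}
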