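test_that("a cohort with no dynamics is static", {
  cfg <- quiet_config(n_injected = 100, homing_prob = 1, r = 0, K = 1e6,
                      n_days = 5, seed = 11)
  sim <- simulate_engraftment(cfg)
  expect_equal(sim$burden$n_cells, rep(100L, 6))
  expect_equal(sim$cells$divisions, rep(0L, 100))
  expect_true(all(sim$cells$true_mfi == cfg$M0))
})

test_that("deterministic doubling: 100 cells become 800 with 3 divisions", {
  cfg <- quiet_config(n_injected = 100, homing_prob = 1, r = 1, K = Inf,
                      n_days = 3, seed = 7)
  sim <- simulate_engraftment(cfg)
  expect_equal(tail(sim$burden$n_cells, 1), 800L)
  expect_equal(unique(sim$cells$divisions), 3L)
})

test_that("label is conserved exactly without noise at every step", {
  cfg <- quiet_config(n_injected = 500, homing_prob = 1, r = 0.6, K = 1e5,
                      d = 0.1, n_days = 8, seed = 3)
  for (day in c(3, 8)) {
    cfg$n_days <- day
    sim <- simulate_engraftment(cfg)
    expect_true(all(sim$cells$true_mfi * 2^sim$cells$divisions == cfg$M0))
  }
})

test_that("mean trajectory follows the discrete logistic map", {
  n_rep <- 12
  cfg <- quiet_config(n_injected = 1e4, homing_prob = 1, r = 0.9, K = 1e6,
                      n_days = 21)
  set.seed(101)
  traj <- sapply(seq_len(n_rep), function(i) {
    simulate_engraftment(cfg)$burden$n_cells
  })
  det <- discrete_logistic(1e4, 0.9, 1e6, 0, 21)
  mc_mean <- rowMeans(traj)
  mc_se <- apply(traj, 1, sd) / sqrt(n_rep)
  # day 0 is exact; later days within 3 Monte-Carlo SE of the map
  expect_equal(mc_mean[1], det[1])
  expect_true(all(abs(mc_mean[-1] - det[-1]) <= 3 * mc_se[-1]))
})

test_that("population cap aborts with a clear message", {
  cfg <- quiet_config(n_injected = 1000, homing_prob = 1, r = 1, K = Inf,
                      n_days = 10, hard_cap = 5e4, seed = 1)
  expect_error(simulate_engraftment(cfg), "hard_cap")
})

test_that("invalid configuration parameters are rejected at construction", {
  expect_error(sim_config(homing_prob = 1.5), "homing_prob")
  expect_error(sim_config(d = 1), "`d`")
  expect_error(sim_config(M0 = -1), "M0")
  expect_error(sim_config(n_injected = 1e6, homing_prob = 1, K = 1e3),
               "carrying capacity")
  expect_error(treatment_plan(1, 0.2, 0.5), "proliferation-dependent")
})

test_that("flow readout is exact without noise and median-preserving with", {
  cells <- data.frame(cell_id = 1:2, divisions = c(3L, 0L),
                      compartment = "active", alive = TRUE,
                      divided_last_day = FALSE,
                      true_mfi = 1000 * 2^(-c(3, 0)))
  fs <- measure_flow(cells, cv_mfi = 0)
  expect_equal(fs$measured_mfi, c(125, 1000))
  big <- make_cohort(1e5, 0, divisions = 0L)
  big$true_mfi <- 1000
  fs2 <- measure_flow(big, cv_mfi = 0.2, seed = 5)
  geo <- exp(mean(log(fs2$measured_mfi)))
  expect_lt(abs(geo - 1000) / 1000, 0.01)
  empty <- cells[0, ]
  expect_error(measure_flow(empty, 0), "empty cohort")
  dead <- cells
  dead$alive <- FALSE
  expect_error(measure_flow(dead, 0), "empty cohort")
})

test_that("treatment kills by division status at the programmed rates", {
  co <- make_cohort(1e5, 0.5)
  plan0 <- treatment_plan(1, 0, 0)
  expect_equal(apply_treatment(co, plan0, seed = 1)$alive, co$alive)

  all_div <- make_cohort(1000, 1)
  wiped <- apply_treatment(all_div, treatment_plan(1, 1, 0), seed = 2)
  expect_equal(sum(wiped$alive), 0L)

  hit <- apply_treatment(co, treatment_plan(1, 0.99, 0.5), seed = 3)
  surv_div <- sum(hit$alive & hit$divided_last_day)
  surv_und <- sum(hit$alive & !hit$divided_last_day)
  # closed-form survival 0.01 vs 0.5 on 5e4 cells each
  expect_lt(abs(surv_div - 5e4 * 0.01), 4 * sqrt(5e4 * 0.01 * 0.99))
  expect_lt(abs(surv_und - 5e4 * 0.5), 4 * sqrt(5e4 * 0.25))
  ratio <- surv_und / surv_div
  expect_gt(ratio, 35)
  expect_lt(ratio, 70)
})

test_that("limiting-dilution engraftment follows the single-hit law", {
  res1 <- simulate_lda(1, doses = c(1, 5), mice_per_dose = 20, seed = 1)
  expect_equal(res1$table$n_engrafted, res1$table$n_mice)
  res0 <- simulate_lda(0, doses = 10, mice_per_dose = 20, seed = 1)
  expect_equal(res0$table$n_engrafted, 0L)
  res <- simulate_lda(0.02, doses = 10, mice_per_dose = 1e5, seed = 42)
  p_true <- 1 - 0.98^10
  frac <- res$table$n_engrafted / res$table$n_mice
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("lda flux readout separates engrafted from non-engrafted mice", {
  res <- simulate_lda(0.1, doses = c(5, 20), mice_per_dose = 30, seed = 9,
                      emit_flux = TRUE)
  calls <- call_engraftment(res$mice$flux)
  expect_equal(calls, res$mice$engrafted)
  expect_equal(
    as.integer(tapply(calls, factor(res$mice$dose, levels = c(5, 20)), sum)),
    res$table$n_engrafted)
})

test_that("expression simulator plants fold-changes and scales libraries", {
  planted <- data.frame(gene = 1:20, log2fc = 3)
  sim <- simulate_expression(500, 40, planted, dispersion = 0.3, seed = 8)
  expect_equal(dim(sim$counts), c(500L, 80L))
  expect_equal(sum(sim$truth$planted), 20L)
  # planted genes shifted in the right direction on average
  m_d <- rowMeans(sim$counts[1:20, sim$groups == "dormant"])
  m_a <- rowMeans(sim$counts[1:20, sim$groups == "active"])
  expect_gt(median(log2((m_d + 1) / (m_a + 1))), 1.5)

  half <- simulate_expression(2000, 50, NULL, dispersion = 0.3,
                              lib_size_factor = 0.5, seed = 9)
  tot_d <- mean(colSums(half$counts[, half$groups == "dormant"]))
  tot_a <- mean(colSums(half$counts[, half$groups == "active"]))
  expect_lt(abs(tot_d / tot_a - 0.5), 0.03)

  expect_error(simulate_expression(100, 10, dispersion = 0), "dispersion")
  expect_error(
    simulate_expression(10, 5, data.frame(gene = 50, log2fc = 1)),
    "universe")
})

test_that("seeds reproduce cohorts bit-identically and differ otherwise", {
  cfg <- sim_config(n_injected = 2e4, homing_prob = 0.1, r = 0.7, K = 1e4,
                    n_days = 10, seed = 123)
  s1 <- simulate_engraftment(cfg)
  s2 <- simulate_engraftment(cfg)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$burden, s2$burden)
  cfg$seed <- 124
  s3 <- simulate_engraftment(cfg)
  expect_false(identical(s1$burden$n_cells, s3$burden$n_cells))
})

test_that("re-transplant re-randomizes dormancy: label-selected and bulk
           transplants seed the same dormant fraction", {
  cfg <- sim_config(n_injected = 3e4, homing_prob = 1, r = 0.5, K = 1e6,
                    d = 0, p_dormant_seed = 0.05, p_wake = 0, p_sleep = 0,
                    dormant_div_rate = 0, n_days = 6, cv_mfi = 0,
                    seed = NULL)
  set.seed(77)
  primary <- simulate_engraftment(cfg)
  fs <- measure_flow(primary, cv_mfi = 0)
  # select label-retaining (low-division) cells only
  keep <- fs$divisions_truth <= 3
  lrc_cells <- primary$cells[keep, , drop = FALSE]
  bulk_cells <- primary$cells
  recfg <- cfg
  recfg$n_days <- 0
  re_lrc <- retransplant(lrc_cells, recfg)
  re_bulk_cfg <- recfg
  re_bulk <- retransplant(bulk_cells, re_bulk_cfg)
  f_lrc <- re_lrc$burden$n_dormant[1] / re_lrc$burden$n_cells[1]
  f_bulk <- re_bulk$burden$n_dormant[1] / re_bulk$burden$n_cells[1]
  # both re-seed dormancy at p_dormant_seed regardless of selection
  test <- prop.test(c(re_lrc$burden$n_dormant[1], re_bulk$burden$n_dormant[1]),
                    c(re_lrc$burden$n_cells[1], re_bulk$burden$n_cells[1]))
  expect_gt(test$p.value, 0.01)
  expect_lt(abs(f_lrc - 0.05), 4 * sqrt(0.05 * 0.95 / re_lrc$burden$n_cells[1]))
})
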