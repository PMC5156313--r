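# lrcdorm

Quantitative machinery for studying rare **dormant, label-retaining
leukemia cells** in patient-derived xenograft (PDX) models of acute
lymphoblastic leukemia (ALL), written for biostatisticians and
computational biologists who work with dye-dilution, engraftment and
expression data from such models.

A proliferation-sensitive dye (CFSE) is halved between daughters at every
division, so a cell's divisions can be counted from its fluorescence:
`k = round(log2(M0 / MFI))` against a pre-proliferation reference `M0`.
Cells with at most three bisections after weeks of leukemic growth are
**label-retaining cells (LRC)** — a rare dormant compartment that survives
chemotherapy, resembles minimal residual disease (MRD, < 1% marrow
blasts), and loses its adverse phenotype when removed from the niche.
`lrcdorm` provides:

* **Simulator** — a stochastic, discrete-day birth–death model of
  label-diluting growth: independent marrow homing, logistic
  niche-limited division (per-day division probability `r(1 − N/K)`), a
  reversible dormant compartment, lognormal flow readout, bioluminescence
  fluxes, proliferation-dependent drug kill, limiting-dilution designs
  and negative-binomial expression matrices with planted signal — with
  truth columns throughout.
* **Gating** — reference calibration, bisection counting, LRC / others /
  non-LRC classification with Wilson intervals, LRC kinetics.
* **Growth** — homing efficiency, exponential vs logistic fits on the
  log scale with `N(t) = K / (1 + (K/N0 − 1)e^{−rt})`, AICc model
  selection.
* **Limiting dilution** — single-hit Poisson MLE of the initiating-cell
  frequency, `P(engraft | d) = 1 − (1 − f)^d`, profile-likelihood 95%
  CIs, goodness of fit, frequency comparison by likelihood ratio.
* **Drug effect** — per-class survival fractions, relative drug effect
  (elimination of LRC as % of non-LRC elimination), LRC enrichment folds,
  MRD calling.
* **Signatures** — rank-sum differential expression with BH-FDR,
  signature derivation (FDR ≤ 0.05, |log2FC| > 1), hypergeometric
  overlap, fold-change sign concordance, permutation rank enrichment.

See `vignettes/dormancy-pipeline.Rmd` for the models, parameter meanings
and design choices.

## Worked example

Simulate a labeled graft for three weeks, calibrate the division counter
on a pre-proliferation aliquot, gate the final sample, and ask whether
the burden curve grew exponentially or logistically:

```r
library(lrcdorm)

cfg <- sim_config(n_injected = 1e5, homing_prob = 0.01,
                  p_dormant_seed = 0.01, n_days = 21, seed = 42)
sim <- simulate_engraftment(cfg)

ref_cfg <- cfg; ref_cfg$n_days <- 0   # post-bleaching reference harvest
ref_sample <- measure_flow(simulate_engraftment(ref_cfg), cv_mfi = 0.2,
                           seed = 1)
ref <- calibrate_reference(ref_sample)

day21 <- measure_flow(sim, cv_mfi = 0.2, seed = 2)
gs <- classify_cells(day21, ref)

ser <- data.frame(day = sim$burden$day, burden = sim$burden$n_cells)
sel <- select_model(list(fit_exponential(ser), fit_logistic(ser)))
```

This prints (reference ≈ 998 against a true `M0` of 1000):

```
   LRC others nonLRC
    16    138 941075
LRC fraction 0.0017% (95% CI 0.0010%-0.0028%)

       model    loglik k criterion    delta
    logistic  33.14664 4 -55.94035   0.0000
 exponential -27.24332 3  61.81997 117.7603
selected: logistic
```

After a ~1000-fold expansion, 16 of ~940,000 cells still carry
near-undiluted label — the rare dormant compartment — and AICc prefers
the logistic growth model by a wide margin (Δ ≈ 118).

Limiting dilution from an engraftment table:

```r
fit_single_hit(data.frame(dose = c(3, 10, 30), n_mice = 20,
                          n_engrafted = c(2, 8, 17)))
# initiating-cell frequency 1/19 (95% CI 1/13-1/28), GOF p = 0.69
```

## Analysis workflow

Numbered drivers under `analysis/` run the full study on simulated
cohorts and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | six-mouse cohort, homing spanning two orders of magnitude; burden series and flow aliquots |
| `02_gating.R` | reference calibration, gating, LRC kinetics over days 0–21 |
| `03_growth.R` | homing efficiencies; exponential vs logistic selection per animal |
| `04_lda.R` | limiting-dilution comparison of sorted LRC vs non-LRC initiating-cell frequencies |
| `05_treatment.R` | day-7 proliferation-dependent chemotherapy: survival by class, relative drug effect, LRC enrichment, MRD call |
| `06_signature.R` | dormancy signature derivation and overlap / concordance / rank-enrichment comparison across cohorts |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

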