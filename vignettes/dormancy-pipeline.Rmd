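---
title: "Quantifying dormant label-retaining leukemia cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dormant label-retaining leukemia cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcdorm)
```

`lrcdorm` implements the quantitative machinery for studying rare dormant
(label-retaining) subpopulations in xenograft models of acute lymphoblastic
leukemia: a stochastic simulator of label-diluting, niche-limited growth,
and the inference steps applied to such data — division counting and LRC
gating, growth-model selection, limiting-dilution stem-cell frequency
estimation, differential drug-effect statistics, and signature derivation
and comparison. This vignette explains the models, the parameters that
matter, and the design choices behind them.

## The simulation model

A cohort of `n_injected` cells is injected intravenously; each cell homes
independently to the bone marrow with probability `homing_prob`. Homing
efficiencies differ enormously between leukemia samples — the simulator
treats the probability as sample-specific and lets drivers span two or
more orders of magnitude across animals.

The homed graft then evolves in **discrete daily steps** with binomial
draws. Each day, in order:

1. **Compartment switching.** Dormant cells wake with probability
   `p_wake`; active cells fall dormant with probability `p_sleep`. Both
   are memoryless per-day probabilities, so dormancy carries no hidden
   state — this implements reversibility without asserting a mechanism.
2. **Death.** Every cell dies with probability `d`.
3. **Division.** An active cell divides with probability
   `r (1 - N/K)`, floored at zero, where `N` is the day-start population
   and `K` the niche carrying capacity; both daughters inherit the
   parent's division count plus one. Dormant cells divide with the small
   constant probability `dormant_div_rate`, not density-limited.

The `(1 - N/K)` scaling makes the expected trajectory follow a discrete
logistic map; a growth curve that is log-linear early and saturates late
is exactly what burden data from such grafts show, and what the fitting
module is designed to detect. The mechanism — rate limitation, consistent
with insufficient nutrient supply — is a modelling choice: burden data
alone identify the logistic shape, not its cause.

Each division halves the cell's true label intensity:
`true_mfi = M0 * 2^-divisions`. `M0` is defined as the day-3 post-bleaching
value, so photobleaching before day 3 is deliberately not simulated. The
flow readout multiplies the true MFI by a median-preserving lognormal
factor with coefficient of variation `cv_mfi`, so the geometric mean of a
sample of undivided cells stays centred on `M0` at any noise level.

Dormant cells can be seeded at engraftment (`p_dormant_seed`) or induced
later by the niche (`p_sleep`). Which of the two happens in vivo is not
known; the simulator exposes both and takes no position. On
re-transplantation (`retransplant()`) the label is reset and compartments
are re-randomized from `p_dormant_seed` — any selected subpopulation
therefore regenerates the same dormant fraction as a bulk transplant,
which is the reversibility property the re-transplant experiments show.

### Default parameter choices

| Parameter | Default | Meaning |
|---|---|---|
| `n_injected` | 1e7 | injected dose (cells), the standard tail-vein dose |
| `homing_prob` | 0.005 | marrow homing probability; sample-specific, order 1e-3 |
| `r` | 0.9 /day | active division rate; ~2-fold daily expansion early |
| `K` | 1e6 | niche capacity at desk scale (see *Problem sizes*) |
| `d` | 0.05 /day | death probability |
| `p_dormant_seed` | 0.01 | dormant fraction among engrafting cells |
| `p_wake`, `p_sleep` | 0.01, 0.001 /day | compartment exchange rates |
| `dormant_div_rate` | 0.01 /day | residual dormant division rate |
| `M0`, `cv_mfi` | 1000, 0.2 | day-3 reference MFI and readout noise |
| `photons_per_cell` | 100 /s | bioluminescence yield |
| `detection_threshold` | 5e5 /s | imaging detection limit for engraftment |
| `n_days` | 21 | horizon of the standard label-dilution experiment |

With these defaults a graft expands by orders of magnitude within three
weeks while a ~1% seeded dormant compartment persists with nearly
undiluted label — the regime in which LRC gating, differential kill and
enrichment statistics operate. The dormancy rates are chosen so that
dormant cells undergo well under one division per three weeks, clearly
separated from the ~1/day active rate.

## Division counting and LRC gating

The day-3 reference MFI is calibrated from a day-3 flow sample
(`calibrate_reference()`), by default with the geometric mean: readout
noise is multiplicative, and for a median-preserving lognormal the
geometric mean is a consistent estimator of the true reference. The
maximum would also mark the undivided peak but is fragile to a single
bright outlier; the median and a log-scale density mode are available
alternatives.

Estimated divisions are `round(log2(reference / mfi))`, clipped below at
zero (`count_divisions()`). The default gate calls a cell **LRC** at no
more than three bisections and **non-LRC** at seven or more — seven
halvings put the label below 1% of the reference, the conventional
definition of complete signal loss — with an intermediate **others**
class.

Classification (`classify_cells()`) thresholds the MFI at the
*half-bisection midpoints*, `reference * 2^-(k + 0.5)`, which makes the
gate identical to thresholding the rounded division count. A cell at
exactly three bisections is LRC and a cell at exactly seven is non-LRC
(boundary inclusive). The midpoint placement matters under noise: a gate
drawn exactly at `2^-3` would lose half of the genuinely three-times
divided cells to any symmetric noise and systematically understate the
LRC fraction, while the midpoint gate is unbiased to first order. Residual
bias remains when neighbouring division bins are very unequal in size
(misrounding flows more mass in from the heavier bin); it grows with
`cv_mfi` and is negligible at `cv_mfi` ≲ 0.1.

## Growth-model fitting and selection

Burden series are fitted on the log scale, treating noise as
multiplicative lognormal — the natural model for counts spanning orders
of magnitude. The exponential model is ordinary least squares of log
burden on day. The logistic model fits
`N(t) = K / (1 + (K/N0 - 1) e^{-rt})` by nonlinear least squares in the
parameterization `(log N0, r, log K)`, multi-started with `N0` at the
first observation, `r` from the early log-slope, and `K` at 2, 10 and 100
times the maximum observed burden. When no start converges the likelihood
is flat in `K` (no saturation in the data); the fit then falls back to
the exponential limit with `K` pinned at a boundary value, flagged
`K_unidentifiable` and `converged = FALSE`. A converged fit is also
flagged when the log-`K` standard error exceeds 2 or `K` lands more than
a thousand-fold above the observed maximum.

Model selection uses AICc on the log-scale Gaussian likelihood (small
series, multiplicative noise); BIC is available by flag. A margin of less
than 2 between candidates is reported as *equivocal* rather than forced.
Fits carry a fingerprint of their input series, and `select_model()`
refuses to compare fits made on different data.

## Limiting-dilution analysis

Under the single-hit model, a transplant of `d` cells engrafts iff it
contains at least one initiating cell: `P(engraft | d) = 1 - (1 - f)^d`.
`fit_single_hit()` maximizes the binomial likelihood over `log f` and
inverts the profile likelihood at the `qchisq(0.95, 1)/2 = 1.92` drop for
the confidence interval — the standard construction behind
limiting-dilution calculators; a Wald interval on `log f` is available
for comparison. All-negative and all-positive tables produce one-sided
bounds with explicit flags instead of errors. Goodness of fit is a
likelihood-ratio test against the saturated per-dose model, which is
exactly a test of the single-hit property that `-log(1 - P(engraft))` be
linear in dose. Frequencies are reported both as numbers and in the
conventional "1 in n cells" form. Two designs are compared with a
likelihood-ratio test of a common frequency (`compare_frequencies()`),
with a warning when an estimate lies on the boundary, where the
chi-squared reference is approximate.

Engraftment itself is called from the imaging readout: flux at or above
the detection threshold (default 5e5 photons/s, inclusive) scores
positive (`call_engraftment()`).

## Drug-effect statistics

Treatment acts through a proliferation-dependent kill: on each scheduled
day, cells that divided within the preceding day die with
`kill_prob_divided`, all others with `kill_prob_undivided`. Per-class
survival fractions are treated-over-control counts with a
conditional-binomial (Poisson-ratio) interval. The **relative drug
effect** expresses the elimination (one minus survival) of LRC as a
percentage of the elimination of non-LRC: 100 means equal kill, 1 means
a hundred-fold less efficient elimination of LRC. It is dimensionless and
scale-free in the counts. Per-mouse effects are computed first and then
averaged, rather than pooling cells across mice.

LRC **enrichment** is the post/pre ratio of LRC fractions, with a
delta-method interval on the log fold. **MRD** is called at a burden
strictly below 1% marrow blasts, with a molecular-remission-like tier
below 0.1%; both thresholds are arguments.

## Expression signatures

The expression simulator draws negative-binomial counts with lognormal
per-gene baselines, plants specified log2 fold-changes in the dormant
group, and can scale the dormant group's library sizes globally below one
to emulate the reduced RNA content of dormant cells.

Differential expression is a per-gene two-sided Wilcoxon rank-sum test on
counts normalized to the median library depth, with Benjamini–Hochberg
correction and pseudocount-1 log2 fold-changes. The implementation is a
vectorized normal approximation with tie and continuity corrections,
cross-checked against `stats::wilcox.test` in the test suite; it exists
so that null-calibration experiments over hundreds of replicate matrices
run in seconds. It deliberately does not attempt to reproduce any
specific single-cell DE toolchain — the aim is a self-contained, testable
stage, not re-derivation of published gene lists.

A signature is the set of genes at FDR ≤ 0.05 and |log2 fold-change| > 1
(both arguments; the fold-change bound is applied symmetrically to both
directions), split by direction and ranked by significance. With two DE
tables — e.g. a bulk and a single-cell analysis — a gene must pass in
both with a consistent direction and is ranked by its worse p-value.

Signatures are compared three ways: exact hypergeometric overlap
(optionally direction-aware: up-with-up plus down-with-down),
fold-change sign concordance with a binomial test against 0.5, and a
weighted running-sum rank enrichment score with a gene-label permutation
null. The enrichment p-value is two-sided on the score magnitude, which
makes it uniform for a randomly placed signature; gene-label (rather than
phenotype) permutation keeps the null seedable and fast at desk scale.

## Numerical choices and degenerate inputs

* Probabilities and thresholds are validated at construction; invalid
  configurations fail before any simulation runs.
* Empty flow samples, empty cohorts, all-zero genes, zero control counts
  and boundary LDA tables all take explicit, documented paths (errors
  with the offending ids, carried-through rows, warnings, one-sided
  flags) rather than propagating NaNs.
* Zero burdens are left-censored at half the detection limit with a
  warning before log-scale fitting.
* The logistic fit is bounded below at `K >= max(burden)` and the
  single-hit likelihood clamps engraftment probabilities away from 0 and
  1 to keep boundary tables finite.
* Ties in the rank-sum statistic use the standard variance correction;
  all-tied genes get p = 1.

## Problem sizes

Simulations in the drivers, tests and acceptance script run at a desk
scale chosen so the full suite completes in minutes: niche capacity 1e6
cells, grafts of 1e2–5e4 homed cells, 500-replicate coverage studies,
200-replicate selection and null-calibration studies. These sizes are the
package's own choice of study conditions; the statistical structure
(orders-of-magnitude growth span, ~1% dormant seeding, 10–100-fold
differential kill) is preserved, while absolute cell numbers are roughly
three orders of magnitude below a real marrow.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the inference modules
assume: sample-specific homing spanning two orders of magnitude, logistic
in-vivo growth, a rare label-retaining compartment persisting over weeks,
strongly differential kill of recently divided cells, reversibility on
re-transplant, and a planted transcriptomic program separating dormant
from cycling cells. It does not model spatial niche structure or
endosteal distances, pharmacokinetics, clonal genetics, spectral
compensation or doublets in flow data, or the technical structure of real
single-cell libraries (dropout, batch). Passing tests therefore
demonstrate that the inference procedures are correct and calibrated for
data with the assumed structure — not that real data satisfy those
assumptions.

## Known limitations

* The daily-step discretization caps division at one per cell per day;
  rates `r` near or above 1/day compress multi-division days into
  successive days.
* At saturation (`N ≈ K`) active cells nearly stop dividing, so
  late-harvest grafts that homed close to capacity retain label for
  kinetic rather than dormancy reasons; drivers keep grafts well below
  capacity at engraftment.
* The LRC gate's residual misrounding bias under heavy readout noise
  (`cv_mfi` ≳ 0.3) is not corrected; deconvolution of the MFI mixture is
  out of scope.
* Profile intervals for frequencies near 1 and likelihood-ratio
  comparisons with boundary estimates are approximate, and flagged as
  such.
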