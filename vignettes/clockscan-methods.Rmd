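---
title: "Methods: clock application under missingness, mortality association, and CpG ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clock application under missingness, mortality association, and CpG ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cluster-averaged epigenetic clocks compress hundreds of thousands of CpG
methylation fractions (beta values in $[0,1]$) into per-cluster averages of
correlated probes, then map those averages to an age-like score. Two
analysis questions arise when such a clock is taken to a cohort measured on
a *different* array platform:

1. Does the clock's **standardized delta age** — predicted minus
   chronological age, divided by the cohort SD of those deltas — predict
   mortality after adjusting for demographics and blood cell composition,
   even when roughly half of the clock's CpGs were never measured?
2. Which individual CpGs **drive** that mortality association? This is
   answered by a leave-one-out style scan: set each clock CpG to zero,
   re-apply the clock, refit the survival model, and watch the
   association's FDR move.

`clockscan` implements this pipeline end to end, plus a synthetic-cohort
generator with a complete truth ledger, so every statistical property is
testable without access-restricted cohort data.

## Clock model and missingness rule

A clock is `intercept + sum_k w_k * xbar_k`, where `xbar_k` is the mean
beta of cluster $k$'s probes. Under missingness the rule is deliberately
simple: missing inputs are removed from the averaging (the mean runs over
available probes only), and a cluster with *no* available probe is set to
zero. The linear-in-cluster-averages form is the minimal form consistent
with cluster averaging; the clock file format carries an explicit
`form: linear_cluster_mean` tag so other response shapes can be added
without ambiguity.

Two consequences worth knowing:

* Because probes within a cluster are correlated, dropping half of them
  perturbs the cluster mean only slightly — this is why a 50% platform
  mask degrades predictions gracefully.
* A *fully* unmeasured cluster snaps to zero, which shifts every sample's
  prediction by the constant `-w_k * xbar_k`. A location shift is
  invisible to the Cox partial likelihood but does move the absolute
  standardized-delta scale; with the default 20-probe clusters a fully
  masked cluster is rare.

Delta standardization uses the sample SD (divisor $n-1$). Predictions are
summarized by $R^2$ (squared Pearson correlation), MAE and RMSE. Beta
values outside $[0,1]$ are rejected at load time rather than clamped
(arrays deliver fractions; out-of-range cells mean a broken upstream
step), and missingness is encoded as `NA`, never as a sentinel number.

## Cell-type deconvolution

Blood composition confounds methylation-mortality associations, so the
Cox model adjusts for neutrophil (N), lymphocyte (L), monocyte (M) and
non-immune (NI) fractions. Fractions are estimated by reference-based
deconvolution in two stages: broad types first (epithelial, fibroblast,
immune), then the immune compartment resolved into blood subtypes, with
final subtype fractions equal to the stage-2 composition times the
stage-1 immune mass. The aggregates are fixed definitions:
`L = CD8T + B + CD4T`, `NI = fibroblast + epithelial`; NK, when the
reference carries it, is reported raw and deliberately excluded from both
L and NI.

The solver is simplex-constrained least squares, made exact by exhaustive
active-set enumeration: for every subset of cell types allowed to be
nonzero, the equality-constrained KKT system is solved and the feasible
candidate with the smallest residual wins (ties by minimum norm,
tolerance `1e-8`). With at most eight cell types this enumerates at most
255 tiny linear systems per sample — exactness is cheaper than cleverness
here. The stage-2-only fit implicitly assumes non-immune mass projects
onto the immune centroid; the induced bias scales with the non-immune
fraction and is negligible in blood.

## Survival model

The proportional-hazards model is fit exactly as the analysis formula
states: time variable = age at death or censoring, event indicator =
status, covariates = standardized delta age, N, L, M, NI, sex,
chronological age at last measurement, cohort, and measurement wave.
Chronological age therefore appears twice (in the time scale and as a
covariate); no left truncation is applied, mirroring the formula as
printed — delayed entry is a flagged extension, not a default. Ties use
the Efron correction (Breslow available). Factors get treatment
contrasts with the lexicographically first level as reference; CIs are
Wald at 95%; per-term p-values are Wald; q-values are Benjamini–Hochberg
across the terms of the single fitted model, matching a forest plot's
per-row FDR column. Whether that multiplicity family should instead span
several models is not decidable from the method description; within-model
is the choice made here and used consistently, including inside the
ablation scan.

Standardized deltas are stratified into $[-3,0)$, $[0,3)$ and $[3,6]$
bins; values outside $[-3,6]$ go to the nearest terminal bin with a
warning (the bins assume an approximately centered standardized delta).
Marginal adjusted survival curves average each stratum member's predicted
curve $S_i(t) = \exp(-H_0(t)\,e^{x_i\beta})$ pointwise, with $H_0$ the
Breslow baseline cumulative hazard computed from the fit; with all
coefficients zero this reduces *exactly* to the Nelson–Aalen estimator,
which the tests assert. The median survival age of a stratum is the first
grid age at which the marginal curve reaches 0.5 or below; a curve that
never crosses reports "not reached" (`NA`).

## The ablation scan

For every CpG shared between the clock and the matrix, the scan:

1. updates the CpG's cluster average — mode `"zero"` sets the beta to 0
   but keeps the denominator (`(sum - beta)/count`); mode `"remove"`
   drops it (`(sum - beta)/(count - 1)`, 0 if the cluster empties).
   `"zero"` is the default because the method description is operational
   about setting CpGs to zero, while `"remove"` matches the looser
   "removed" phrasing; both are implemented and tested.
2. recomputes predictions incrementally (only the probe's own cluster
   changes, so the update is a rank-one correction to the prediction
   vector) and re-standardizes deltas, by default with the ablated
   predictions' own SD (`freeze_sd = TRUE` reuses the base SD; the method
   description does not say which was used, so both are available),
3. refits the full Cox model with the updated standardized delta — all
   other covariates held fixed — and records the delta term's q-value.

The incremental path is bit-for-bit equivalent to naively rebuilding the
matrix and recomputing everything per probe; the suite verifies equality
of q-values to `1e-12` in both modes. A CpG's **impact** is the fold
change `ablated_q / base_q`: impact above 1 means its removal weakened
the association (a *mortality* CpG), below 1 strengthened it
(*anti-mortality*), exactly 1 (e.g. a probe the platform never measured)
is neutral. Records are sorted by descending impact and ranked; refit
failures are recorded and skipped, never silently dropped. The scan is
embarrassingly parallel over probes and merged deterministically by probe
id; identical inputs give byte-identical tables.

Top annotated genes per class take the first $k$ (default 250) *annotated*
records in impact order (mortality: descending; anti-mortality:
ascending), de-duplicated, skipping unannotated CpGs without counting
them. Enrichment is plain hypergeometric over-representation against GMT
gene sets (one-sided tail $P(X \ge \text{overlap})$, BH across sets,
flag at FDR 0.05). Network-topology enrichment over a PPI graph is
explicitly out of scope; ORA is the substitute.

## The synthetic cohort generator

The generator defines the study conditions and is fixed:

* **Cohort**: 1,000 samples, ages uniform on 67.8–90.6 years, two cohort
  labels, four waves, blood-like Dirichlet cell mixtures
  (neutrophil-dominated, trace epithelial/fibroblast, NK present so the
  four fraction covariates do not sum to one and stay identifiable).
* **Clock**: 2,000 CpGs in 100 clusters. Clusters are correlated probe
  sets: probes share a cluster-level baseline (SD 0.02 around it) and age
  slope (10% relative spread), with slope sign following the cluster
  weight. Weights and intercept are calibrated analytically so the
  noise-free clock output equals chronological age. Per-probe beta noise
  SD is 0.03; values are clamped to $[0,1]$ after noise (a documented
  small bias at the extremes, preferred over truncated sampling for
  simplicity).
* **Delta spread**: a latent person-level aging offset (SD 3 years) is
  added to the effective age each probe responds to; the calibrated clock
  reads it out as delta age, giving deltas a realistic ~4–5 year SD
  instead of pure measurement noise.
* **Platform mask**: exactly `floor(0.5 * 2000)` clock probes retained,
  drivers always among them (an unmeasured driver cannot be ranked).
* **Driver planting**: one CpG is rewired into its own singleton cluster
  whose weight is set analytically so the driver's contribution to delta
  SD equals the whole non-driver delta SD (`driver_frac = 1`); its beta
  carries `0.5 + 0.12 * m_i` with `m_i` latent standard normal. The
  hazard sees `m_i` only through the realized standardized delta, so the
  driver is "important" in exactly the sense the scan measures.
* **Survival**: Weibull baseline on the age scale (shape 8, scale 97 —
  chosen so the event fraction lands near 40% under 12-year per-person
  follow-up with a hard cap at age 105), multiplier
  `exp(b_true * s_delta + 0.25 * male)`, `b_true = log(1.21)` per SD.
  Event ages are drawn conditional on survival to study entry; the
  analysis model (faithfully) ignores that truncation, and because the
  standardized delta is independent of entry age the induced attenuation
  is far below the coefficient's standard error.

What the generator does **not** emulate: array artifacts (dye bias,
detection p-values, batch effects), probe-level biological annotation
structure, genuine correlation between cell composition and clock CpGs,
and informative censoring. Passing tests therefore demonstrate the
*statistical machinery* — estimator correctness, exactness of the
incremental scan, calibration and power at the configured effect sizes —
not fidelity to any particular real cohort.

## Numerical and design choices

* Cox fits run through the standard partial-likelihood Newton solver; the
  test suite checks coefficients against dense grid maximization of the
  exact partial likelihood on small untied datasets (absolute 1e-3).
* Scan refits use the same cold-start iteration path as the base fit, so
  the incremental-vs-naive equality holds to floating-point rounding
  rather than to optimizer tolerance.
* BH q-values come from the standard step-up; an independently written
  step-up oracle in the tests agrees to machine rounding on 1,000 random
  p-vectors.
* Under a zero clock-mortality effect, per-cohort ablation q-shifts are
  strongly *correlated* across probes (each ablation removes a small
  age-correlated component, and the shift direction is set by the
  cohort's chance correlations). Balance of mortality vs anti-mortality
  calls therefore holds across cohorts, not within one: the calibration
  test uses the seed as the sampling unit (sign test of the per-seed
  majority direction across 20 seeds). A pooled binomial test over all
  CpGs would be grossly overdispersed and is deliberately not used.
* Problem sizes in the suite: exactness checks at 100 samples x 200
  probes; recovery, masking-robustness and calibration checks at the
  default 1,000 x 2,000 over 20–50 seeds. These sizes give the
  statistical checks comfortable power while keeping the suite quick to
  run.

## Known limitations

* The clock's true internal architecture (any nonlinearity between
  cluster averages and age) is unknowable from the outside; only the
  linear form is implemented.
* The deconvolution stands in for reference-based methods with published
  reference matrices; synthetic signatures ship instead of the published
  ones, and externally computed proportions can be supplied to bypass the
  module entirely.
* Stratified hazard ratios for the extreme $[3,6]$ bin are unstable in
  cohorts whose standardized deltas are approximately centered (the bin
  holds a handful of samples); the continuous per-SD model is the primary
  analysis.
* No time-varying covariates, competing risks, frailty, or left
  truncation.

## A worked example

```{r, eval = FALSE}
library(clockscan)

cfg <- simulation_config(seed = 1)
cohort <- simulate_cohort(cfg)

fit <- fit_cox(cohort$table)
print(fit)

scan <- ablation_scan(cohort$beta[, cohort$clock$probe_ids],
                      cohort$clock, cohort$table,
                      annotation = cohort$annotation)
print(scan)
```

The README shows this example with the numbers it prints.
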