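# clockscan

Mortality association and per-CpG ablation scanning for cluster-averaged
epigenetic clocks, under arbitrary probe missingness.

## The problem

Epigenetic aging clocks map DNA methylation beta values (fractions in
[0, 1] at CpG probes) to an age-like score. Cluster-averaged clocks first
collapse correlated CpGs into per-cluster means, then take a weighted sum:

    predicted age = intercept + Σ_k w_k · x̄_k

where `x̄_k` is the mean beta of cluster *k*. When such a clock — trained
on one array platform — is applied to a cohort measured on another,
roughly half of its CpGs may simply not exist in the data. `clockscan`
applies the clock anyway, using the rule that missing inputs are removed
from the averaging and clusters with no available CpG are set to 0.

For a longitudinal cohort, the package then asks two questions:

1. **Does the clock capture mortality risk?** The standardized delta age
   `sΔ = (predicted − chronological) / SD(deltas)` enters a Cox
   proportional-hazards model on the age timescale,

       Surv(SurvAge, Status) ~ sΔ + N + L + M + NI + Sex + Age + Cohort + Timepoint,

   with neutrophil (N), lymphocyte (L = CD8T + B + CD4T), monocyte (M)
   and non-immune (NI = fibroblast + epithelial) fractions estimated by
   reference-based, simplex-constrained deconvolution. Per-term hazard
   ratios come with Wald 95% CIs and Benjamini–Hochberg FDR q-values;
   delta strata ([−3,0), [0,3), [3,6] SD) get marginal adjusted survival
   curves from the Breslow baseline hazard, with median survival ages.

2. **Which CpGs drive the association?** The ablation scan sets each
   clock CpG to zero (or removes it), re-applies the clock through an
   exact incremental update, refits the full Cox model, and records the
   FDR of the sΔ term. The fold change `ablated q / base q` ranks every
   CpG: impact > 1 marks a *mortality* CpG (its removal weakens the
   association), impact < 1 an *anti-mortality* CpG. Top annotated genes
   per class feed a hypergeometric over-representation analysis against
   GMT gene sets.

Because real cohorts of this kind are access-restricted, the package
includes a first-class synthetic-cohort generator
(`simulate_cohort()`) producing clock, methylation, cell mixtures,
platform masks, and survival with known ground truth (including a planted
driver CpG), so every statistical property of the pipeline is testable.

## Worked example

```r
library(clockscan)

cfg    <- simulation_config(seed = 1)   # 1,000 samples, 2,000 CpGs, 50% measured
cohort <- simulate_cohort(cfg)

fit <- fit_cox(cohort$table)
print(fit)
#> Cox proportional-hazards fit: n = 1000, events = 402, ties = efron
#>         term    n     hr ci_low  ci_high        p        q
#>      s_delta 1000 1.2160 1.1020   1.3410 9.21e-05 5.07e-04
#>            N 1000 2.4070 0.2439  23.7600 4.52e-01 6.22e-01
#>            L 1000 1.0850 0.1132  10.3900 9.44e-01 9.44e-01
#>            M 1000 1.6160 0.1211  21.5500 7.17e-01 7.88e-01
#>           NI 1000 3.8600 0.1379 108.0000 4.27e-01 6.22e-01
#>         SexM 1000 1.4320 1.1750   1.7460 3.78e-04 1.39e-03
#>          Age 1000 0.8848 0.8630   0.9071 5.73e-22 6.30e-21
#>  CohortC1936 1000 1.1530 0.9456   1.4060 1.59e-01 2.92e-01
#>  TimepointW2 1000 1.2230 0.9301   1.6080 1.50e-01 2.92e-01
#>  TimepointW3 1000 1.2610 0.9494   1.6760 1.09e-01 2.92e-01
#>  TimepointW4 1000 1.0710 0.8033   1.4290 6.39e-01 7.81e-01
```

The simulated truth is a hazard ratio of 1.21 per SD of standardized
delta: the fit recovers 1.216 (CI 1.10–1.34, q = 5.1e-4). The Age hazard
ratio below 1 is the expected artifact of using age both as the time
scale and as a covariate (later entry at the same hazard age implies
lower risk); it is adjustment, not biology.

```r
scan <- ablation_scan(cohort$beta[, cohort$clock$probe_ids],
                      cohort$clock, cohort$table,
                      annotation = cohort$annotation)
print(scan)
#> Ablation scan (mode 'zero'): 2000 CpGs, base q = 0.000507
#>   mortality: 583, anti-mortality: 417, neutral: 1000, failed: 0
#> Top CpGs by impact:
#>  rank  probe_id    ablated_q   impact     class      gene
#>     1 cg0000450 0.0031328715 6.182421 mortality GENE00660
#>     2 cg0001819 0.0005616438 1.108350 mortality GENE01271
#>     3 cg0000161 0.0005463321 1.078134 mortality GENE00515
#>     4 cg0000326 0.0005380571 1.061804 mortality GENE01265
#>     5 cg0001456 0.0005337287 1.053262 mortality GENE01544

cohort$truth$driver_ids
#> [1] "cg0000450"
```

The planted driver CpG ranks first: removing it raises the mortality
FDR 6.2-fold, while every other measured CpG moves it by at most ~11%.
The 1,000 "neutral" CpGs are the clock probes the simulated platform
never measured — ablating them is exactly a no-op. End-to-end file-based
runs (`run_pipeline()`, or `Rscript inst/scripts/clockscan.R run ...`)
write predictions, the forest table, survival curves, the scan table,
enrichment results and a reproducibility manifest.

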