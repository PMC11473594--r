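Package: clockscan
Title: Epigenetic Clock Mortality Association and CpG Ablation Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Applies cluster-averaged linear epigenetic clocks to DNA
    methylation beta matrices with arbitrary probe missingness, estimates
    cell-type fractions by simplex-constrained reference-based
    deconvolution, tests standardized delta age for mortality association
    with Cox proportional-hazards models on an age timescale, draws
    marginal adjusted survival curves from the Breslow baseline hazard,
    and ranks every clock CpG by its impact on the mortality association
    through an exact incremental set-to-zero ablation scan, with
    hypergeometric over-representation analysis of the top annotated
    genes. Ships a synthetic-cohort generator with known ground truth so
    the whole pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
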