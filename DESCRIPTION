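Package: crossres
Title: Biomarker Panel Discovery for Endocrine-Therapy Cross-Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gene and protein panels that mark cross-resistance to
    both SERM/SERD and aromatase-inhibitor endocrine therapy in
    hormone-receptor-positive breast cancer. Implements z-score outlier
    screening with Venn-region candidate selection, a staged filter cascade
    over survival and fold-change criteria, per-feature optimal cut-off ROC
    scoring with a single-cutoff balanced-accuracy AUC, cumulative binary
    risk scores with PD-anchored dichotomization, and Kaplan-Meier/log-rank
    survival stratification. Ships a synthetic two-cohort generator emulating
    a treatment-response cohort and an endocrine-therapy cohort so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
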