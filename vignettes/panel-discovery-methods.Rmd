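---
title: "Methods: cross-resistance panel discovery with crossres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-resistance panel discovery with crossres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossres)
```

## The problem

Hormone-receptor-positive breast cancer is treated first-line with endocrine
therapy: SERMs (e.g. tamoxifen), SERDs (e.g. fulvestrant) or aromatase
inhibitors. A substantial minority of patients progress on all of these —
*cross-resistance*. crossres implements a discovery pipeline for expression
markers of such cross-resistance from two linked cohorts:

* a **treatment-response (TR) cohort**: samples labelled complete response
  (CR) or progressive disease (PD), with the PD samples annotated by
  first-line regimen (AI vs SERM/SERD);
* an **endocrine-therapy (ET) cohort**: a larger arm without response labels
  but with progression-free (PFS) and overall survival (OS) follow-up.

Expression arrives as z-scored RNA-seq values for all samples and level-3
normalized RPPA protein values for a subset.

## The procedure

1. **Outlier screen.** Within each TR group (CR, AI-PD, SERM/SERD-PD) a
   feature is flagged when at least one group sample lies at `|z| >= 2`
   (boundary inclusive; the minimum flagged fraction is configurable). The
   *candidate region* of the three-set Venn partition is the set of features
   flagged in both PD arms — cross-resistance operationalized as set
   intersection.
2. **Survival significance.** Each candidate dichotomizes the ET cohort by
   its own outlier flag; it survives when the log-rank p-value is below 0.05
   for *both* PFS and OS.
3. **Fold change.** On z-scored (log-scale) data a fold change is a
   difference of group means; a candidate survives when either PD arm
   differs from CR by more than 0.5.
4. **Two-cohort consistency.** Per-feature cutoff rules (below) are fitted
   on the TR response and transferred verbatim to the ET cohort; a feature
   must satisfy at least one TR-arm criterion and one ET-arm criterion.
   The criteria are conjunctions of a response-AUC floor (0.6) and
   strict/relaxed survival p-value thresholds (0.05 / 0.1); each is an
   explicit configuration entry because the criterion lists that inspired
   them are terse, and auditability beats cleverness here.
5. **Panel selection.** Greedy forward selection maximizing the cumulative
   risk score's response AUC (Mann–Whitney), with deterministic tie-breaks
   (higher PFS AUC, then alphabetical).

The RPPA path runs the screen and panel selection only: protein arrays
measure far fewer targets, so the candidate region is already small and the
intermediate filters are unnecessary.

## The per-feature cutoff model (IROC)

For a feature with values \(x_i\) and an unfavored-outcome indicator, every
observed value is tried as a cutoff \(c\) under both directions
(\(x \ge c\) or \(x \le c\) defines "high risk"), and the single-cutoff AUC

\[
\mathrm{AUC} = \frac{TP}{2(TP+FN)} + \frac{TN}{2(FP+TN)}
\]

— the balanced accuracy, i.e. the area under the one-point ROC curve — is
maximized. Ties are broken toward higher sensitivity, then the cutoff
farther from the median, then `>=` before `<=`, so the search is fully
deterministic. Because both directions are searched the optimum is always
at least 0.5. Candidate cutoffs are the observed values themselves (not
midpoints) with inclusive comparison, consistent with the `>= c` / `<= c`
form in which such rules are reported.

**Finite-sample optimism.** The maximized single-cutoff AUC equals
\(\tfrac12 + \tfrac12 D\), where \(D\) is the two-sample
Kolmogorov–Smirnov distance, so under the null its expectation is roughly
\(\tfrac12 + 0.43/\sqrt{n_\mathrm{eff}}\) with
\(n_\mathrm{eff} = n_1 n_2/(n_1+n_2)\). At the TR cohort's size
(34 vs 10, \(n_\mathrm{eff} \approx 7.7\)) a null feature averages an IAUC
near 0.64; the statistic is a ranking device there, not an unbiased effect
estimate. Calibration claims about the null IAUC are therefore checked at
asymptotic sizes (2000 samples), where the optimism has shrunk below 0.02.

## Cumulative risk scores and stratification

A sample's platform score is the count of panel features on whose high-risk
side it falls (missing measurements score 0, keeping totals comparable; the
count of such imputations is logged). The combined score adds the RNA and
RPPA scores where both exist. Score performance is summarized by the
rank-formulation ROC with midranks for ties and a tie-corrected
Mann–Whitney normal approximation against AUC = 0.5; discrimination bands
are acceptable \([0.7, 0.8)\), excellent \([0.8, 0.9)\), outstanding
\([0.9, 1]\), boundaries assigned upward.

The high/low-risk split anchors on the PD group: the threshold is the mean
or median PD score, rounded up when fractional (for integer scores,
"score ≥ mean" is exactly "score ≥ ceiling(mean)"). The ET cohort reuses
the TR-derived threshold unchanged — the validation arm never refits
anything. Stratified groups are compared with Kaplan–Meier curves and the
standard Mantel–Haenszel log-rank test (discrete-time hypergeometric
variance at ties).

## The synthetic cohort generator

The generator exists so every stage is testable without controlled-access
data; its defaults are the study conditions, not knobs:

| parameter | default | rationale |
|---|---|---|
| `n_cr`, `n_pd` | 34, 10 | TR arm composition; even `n_pd` forces a 5/5 AI vs SERM/SERD split among progressors |
| `n_et` | 449 | ET arm size |
| `rppa_subset_fraction` | 32/44 | fraction of samples with protein data, stratified by response |
| `effect_shift` | 1.5 | mean z-shift of planted markers in resistant samples (unit variance) |
| `block_size`, `block_rho` | 10, 0.5 | equicorrelated feature blocks; planted markers are spread one per block so the correlation-matrix view has structure |
| `et_resistance_prevalence` | 0.15 | latent resistance in the unlabelled arm |
| `baseline_hazard` | 1/1200 per day | median progression ≈ 2.3 years; OS hazard is half the PFS hazard |
| `hazard_ratio_pd` | 2.5 | hazard multiplier for resistant samples, PFS and OS |
| `censor_rate` | 0.3 | independent exponential censoring; chosen so roughly two-thirds of subjects have observed events, giving the survival filters non-trivial operating characteristics at these cohort sizes |
| `arm_mix` | AI .50 / SERM .45 / SERD .05 | regimen frequencies |

Feature marginals are standard normal because the pipeline consumes
z-scores; there is no count-level simulation, no batch structure, and real
registry data are censored far more heavily than 30%. Passing tests on this
generator therefore demonstrate the machinery's correctness and its
operating characteristics under clean Gaussian shifts — not performance on
real TCGA-like data.

**What the defaults imply for recovery.** With the screen fixed at
`|z| >= 2` in at least one of 5 samples per PD arm, a planted marker with a
1.5 z-shift passes both arms with probability
\((1-(1-0.31)^5)^2 \approx 0.71\); the ET survival filter then retains
roughly half of the passers at \(\alpha = 0.05\) on both endpoints. Full
planted-panel recovery is therefore *not* expected under these conditions —
the end-to-end tests measure exactly how much of the signature survives,
and the package reports the attrition stage by stage rather than hiding it.

## Numerical and design choices

* **Fisher's exact test** uses probability-mass ordering for the two-sided
  p (sum of all same-margin tables no more probable than the observed one,
  with a `1e-7` relative tolerance); degenerate margins give p = 1. This is
  the convention that reproduces the published contingency-table p-values
  the test suite pins.
* **Wilcoxon** switches from exact enumeration to the tie/continuity
  corrected normal approximation above a combined n of 20 (configurable).
* **Survival-filter dichotomy**: the |z| ≥ 2 outlier flag reuses the
  screen's own threshold; optimal-cutoff dichotomization is available via
  `cascade_config(survival_dichotomy = "rule")`.
* **Panel mode**: `run_cascade()` defaults to fixed panel sizes (RNA 10,
  RPPA 5), the sizes such signatures are reported at; improvement-stop
  mode is available and is the default of `cumulative_panel_selection()`
  itself. Greedy forward selection is a reconstruction — no published
  algorithm exists for the cumulative step — and is declared as such.
* **p-value display** rounds to three decimals with a `<0.001` floor in
  reports only; machine-readable outputs keep full precision.
* **Determinism**: all randomness flows from one integer seed; reports
  embed the seed and a configuration hash, and identical configurations
  produce byte-identical bundles.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (60-120 ET samples, 60 RNA features);
the end-to-end recovery study uses the full default conditions (TR 34+10,
ET 449, 500 RNA / 100 RPPA features, 20 seeds); null calibrations use 1000
replicates and asymptotic checks 2000 samples. These sizes are the
package's chosen experiment design and are stated here so the reported
operating characteristics can be tied to them.

## Known limitations

* The screen's within-group flag is per-sample; a group-mean criterion is
  deliberately not offered because on 5-sample groups it is both less
  standard and nearly degenerate.
* No Cox models, no multivariable adjustment, no AUC confidence intervals:
  the pipeline mirrors a univariate cutoff-based workflow.
* Gene-set enrichment of the final panel is out of scope; the panel is
  exported in plain TSV form suitable for external enrichment tools.
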