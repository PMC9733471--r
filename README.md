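# iraescreen

Integrative screening of **immune-related adverse event (irAE) risk** under
anti–PD-1 therapy across cancer types.

Checkpoint inhibitors can trigger autoimmune-like toxicities, and which
patients are predisposed remains hard to predict. This package is for
biostatisticians and pharmacoepidemiologists who want to join two data
sources at the cancer-type level and ask which baseline immunogenomic
features track irAE risk:

1. **Spontaneous adverse-event reports** (FAERS/OpenVigil-style extracts):
   restricted to anti–PD-1 monotherapy (ipilimumab combinations excluded),
   each report classified by whether ≥ 1 reaction preferred term is on an
   irAE term list, then summarized per cancer type as a **reporting odds
   ratio** against the pooled other cancer types,

   ROR = (a·d)/(b·c),  CI₉₅ = exp(log ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)),

   with the Haldane–Anscombe +0.5 correction when a cell is zero.
2. **Per-patient cohort tables** (TCGA-style): log₁₀(count+1) tumor
   mutational burden, xCell-style immune-cell enrichment scores,
   expression-signature scores from GMT gene sets, checkpoint gene
   expression, the PD-1-high patient proportion (pooled 80th-percentile
   cutoff), and genome-wide mRNA/microRNA/protein features — each aggregated
   to per-cancer-type medians.

On top of the resulting cancer-type × factor matrix it runs

- a **Pearson correlation screen** of every factor against the ROR with
  Benjamini–Hochberg FDR control within each screen family,
- an **exhaustive uni/bi/trivariate linear-model search** scored by
  leave-one-out cross-validated Pearson R (coefficients from the full-data
  fit, performance from LOOCV), screened by variance inflation factors
  (VIF > 4 flags collinearity) and nested log-likelihood-ratio tests against
  every parent model, and
- **independent-cohort validation** of candidate genes: Mann–Whitney tests
  of expression by irAE occurrence (grade ≥ 1) and by grade, plus logistic
  regression adjusting for therapy class.

A synthetic-data generator (`sim_config()`, `simulate_reports()`,
`simulate_cohort()`, `simulate_validation_cohort()`) produces the whole study
with known planted structure, including an exact `expected_ror()` oracle for
what a pooled-comparator disproportionality analysis can recover — so every
stage is testable without any external download.

## Worked example

```r
library(iraescreen)

cfg  <- sim_config(seed = 7, reports_per_type = 5000)
rep  <- simulate_reports(cfg)
mono <- filter_monotherapy(rep$reports)          # anti-PD-1, no ipilimumab
ror  <- ror_by_cancer(mono, irae_terms(rep$truth$irae_terms))
summary(ror)
#> 52782 eligible cases across 21 cancer types; 15936 (30.19%) with >= 1 irAE
#> ROR range: 0.44 (CT18) to 1.43 (CT20)

coh <- simulate_cohort(cfg)
fm  <- median_factor_matrix(coh$patients, coh$omics, ror = ror)
head(as.data.frame(screen_factors(fm))[, 1:6], 5)
#>     factor family  n         r            p reason
#> 1 MIR_0002  mirna 21 0.9866244 1.968911e-16   <NA>
#> 2 MIR_0004  mirna 21 0.9831576 1.734768e-15   <NA>
#> 3 MIR_0001  mirna 21 0.9823166 2.747139e-15   <NA>
#> 4 MIR_0003  mirna 21 0.9705449 3.343183e-13   <NA>
#> 5 MIR_0026  mirna 21 0.7927678 1.823884e-05   <NA>

s <- search_ror_models(fm, candidates = c("DC", "log_TMB", "naiveCD4T",
                                          "CD8_Tcells", "Mast_cells", "Bcells"))
best_model(s, size = 3)
#> Cross-validated linear model of irAE reporting odds ratio
#>   ROR = 4.729 x DC + 0.2335 x log_TMB + 4.557 x naiveCD4T - 0.5734
#>   LOOCV R = 0.973 (p = 1.3e-13), unexplained variance = 0.053
#>   max VIF = 1.14
#>   n = 21 cancer types

predict(best_model(s, size = 3), c(DC = 0.12, log_TMB = 2.1, naiveCD4T = 0.06))
#> [1] 0.7579394
```

Reading the output: the simulated extract yields ~30% of monotherapy cases
with ≥ 1 irAE; the four planted microRNA hits top the genome-wide screen; the
model search recovers the three planted predictors with a cross-validated
R = 0.97 and no collinearity flag (the coefficients are smaller than the
planted ones because the estimated ROR is measured against the *pooled* other
cancer types, which compresses the scale — see the vignette); and `predict()`
applies the full-data formula to a new cancer type's factor medians, as one
would for a cancer type absent from the training panel.

`run_pipeline()` chains all stages (with per-stage TSVs and a JSON run
summary), and `inst/scripts/irae-screen` exposes them as CLI subcommands
(`simulate | ror | features | correlate | modelsearch | predict | validate |
run`). The methods vignette (`vignettes/irae-risk-modelling.Rmd`) documents
the model, thresholds, numerical choices, and the generator's scope.

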