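---
title: "Modelling immune-related adverse event risk across cancer types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immune-related adverse event risk across cancer types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraescreen)
```

## The problem

Immune checkpoint blockade of the PD-1 axis can trigger autoimmune-like
toxicities — immune-related adverse events (irAEs) — ranging from mild rash to
life-threatening colitis, pneumonitis or myocarditis. Whether a tumor's
baseline cellular and molecular makeup predisposes its host to irAEs is a
question that no single clinical trial can answer across cancer types.
`iraescreen` implements an integrative screen that joins two very different
data sources at the level of the *cancer type*:

1. **Spontaneous pharmacovigilance reports.** Each report names suspected
   drugs, an indication (cancer type), and coded reaction terms. Restricting
   to anti–PD-1 monotherapy (combinations with ipilimumab excluded) and
   classifying each report by whether at least one reaction term belongs to
   an irAE preferred-term list yields, per cancer type, a 2×2 table of
   (index type vs all other types) × (irAE vs non-irAE) and hence a
   **reporting odds ratio** (ROR)
   $$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
   \mathrm{CI}_{95} = \exp\left(\log \mathrm{ROR} \pm 1.96
   \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$
   the standard disproportionality statistic for "does this cancer type
   report irAEs more than the others under the same therapy?"

2. **Per-patient immunogenomic factors** from a pan-cancer cohort: the
   log-transformed nonsynonymous mutation count (TMB), immune-cell enrichment
   scores (xCell-style values in $[0,1]$), expression-signature scores,
   checkpoint gene expression, the proportion of PD-1-high patients, and
   genome-wide mRNA/microRNA/protein features. Every factor is aggregated to
   a per-cancer-type **median** (the PD-1-high column is a proportion), giving
   a cancer-type × factor matrix aligned with the ROR outcome vector.

The analysis then proceeds in three stages: a Pearson correlation screen of
every factor against the ROR with Benjamini–Hochberg FDR control; an
exhaustive search of uni-, bi- and trivariate linear models of the ROR scored
by leave-one-out cross-validation (LOOCV); and validation of candidate genes
in an independent patient-level cohort (Mann–Whitney tests by irAE status and
grade, and logistic regression adjusting for therapy class).

## The model core

`ror_model()` fits
$$\mathrm{ROR}_k = \beta_0 + \sum_j \beta_j\, x_{jk} + \varepsilon_k$$
across cancer types $k$ by ordinary least squares and reports two distinct
things deliberately kept apart:

* **Coefficients** come from the full-data fit — these are the formulas a
  reader can apply to a new cancer type via `predict()`.
* **Performance** comes from LOOCV: each cancer type is held out, the model
  refit on the remaining $n-1$, and the pooled held-out predictions are
  correlated with the observed ROR. We report that Pearson $R$, its two-sided
  t-distribution p-value, and the unexplained variance $1 - R^2$.

Pooling held-out predictions before correlating (rather than averaging
per-fold statistics) is the natural choice for leave-one-out, where each fold
yields a single prediction; this choice is fixed and documented here.

`search_ror_models()` enumerates all size-1/2/3 subsets of a candidate list.
A model is *admissible* if

* every likelihood-ratio test against each nested parent (each
  $(k-1)$-subset; the intercept-only model for univariate models) has
  $p < 0.05$, using Gaussian maximum-likelihood log-likelihoods
  ($\hat\sigma^2 = \mathrm{RSS}/n$), and
* no variance inflation factor $\mathrm{VIF}_j = 1/(1-R_j^2)$ exceeds 4,
  with $R_j^2$ from regressing predictor $j$ on its co-predictors.

Both thresholds are arguments, not constants. LOOCV p-values are BH-adjusted
within each model-size family; the correlation screen likewise adjusts within
each family (the curated panel as one family, each omics kind as its own),
since a genome-wide mRNA screen and a 12-factor panel should not share one
multiplicity budget. Both family structures are configurable because
reasonable analysts could pool them differently.

## Numerical choices

* **Zero cells** in a 2×2 table get the Haldane–Anscombe correction (+0.5 to
  all four cells), applied only when a zero is present and only then;
  disabling the correction turns a zero denominator into a classed
  degenerate-statistic error instead of `Inf`.
* **Perfect fits** ($\mathrm{RSS}=0$, e.g. planted noise-free data) floor
  $\hat\sigma^2$ at $10^{-12}$ and set a `degenerate` flag rather than
  returning an infinite log-likelihood; likelihood-ratio statistics are
  clamped at 0 against tiny negative rounding.
* **Perfect collinearity** yields `Inf` VIF with a flag, not an exception, so
  an exhaustive search never aborts mid-enumeration.
* **Ranking ties** break toward fewer predictors, then lexicographic
  predictor names, making search output deterministic.
* **Mann–Whitney**: exact two-sided p by the permutation distribution when
  $n_1 n_2 \le 400$ and no ties are present; otherwise the normal
  approximation with tie and continuity corrections. $U$ counts cross-pairs
  with ties worth one half.
* **PD-1-high** uses the pooled linear-interpolation quantile (default 80th
  percentile) and *strictly above* comparison, so an all-equal cohort has a
  well-defined proportion of 0.
* **TMB** is $\log_{10}(\text{count}+1)$; base and offset are arguments. The
  base rescales coefficients but cannot change correlations or model ranking.
* **Expression preprocessing** is $\log_2(x+1)$ followed by removal of
  features whose per-type median is zero in more than half of the types;
  medians are taken after the log transform. Published pipelines rarely state
  this order; it is fixed and documented here.

## What the synthetic generator emulates

`sim_config()` + `simulate_reports()` / `simulate_cohort()` /
`simulate_validation_cohort()` generate the full study with known planted
structure:

* Per-type factor means are drawn from configurable ranges and combined by a
  planted linear model (defaults: $19.03 \cdot DC + 0.82 \cdot
  \log TMB + 18.03 \cdot naiveCD4T - 1.85$, the published trivariate
  formula used here as a recoverable ground truth) to give each type's true
  ROR; the irAE probability of an anti–PD-1 monotherapy report follows as
  $p_k = \omega_0 \mathrm{ROR}_k / (1 + \omega_0 \mathrm{ROR}_k)$ against a
  reference stratum with background irAE odds $\omega_0$ (default 0.1, which
  puts the overall irAE fraction near the ~29% seen in real extracts).
* Because a disproportionality analysis compares each type against the
  *pooled* other types — whose irAE rate depends on all strata — the nominal
  planted ROR and the ROR a pharmacovigilance analysis can estimate differ
  slightly. `expected_ror()` computes the exact pooled-background value
  implied by the planted probabilities, and convergence tests compare
  estimates against that oracle, not the nominal value.
* Expression is generated on the log2 scale and exponentiated (log-normal,
  nonnegative, right-skewed, TPM-like); planted screen hits act through
  cancer-type mean shifts proportional to the standardized planted ROR, so
  they survive median aggregation. The default factor-mean ranges keep the
  zero-noise minimum ROR near 0.85, inside the 0.94–5.87 span seen in real
  data; configurations whose planted ROR would be nonpositive are rejected
  rather than truncated, because truncation would silently break the planted
  linear truth.
* One global seed feeds a per-table stream-splitting scheme, so adding an
  omics layer cannot perturb the report table, and identical configurations
  are byte-identical.

**What passing tests do and do not show.** The generator plants exactly the
structure the pipeline assumes: linear factor–ROR relationships, independent
reports, exchangeable patients within type, no duplicate reports, no
indication miscoding. Real spontaneous-report data violate several of these
(duplicates, notoriety bias, missing indications), and real cohorts have
batch structure the generator omits. Green tests therefore certify the
statistical machinery — not that the biological associations will replicate
on new data.

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to make their guarantees sharp
but cheap: 20 000 reports per type for ROR convergence (binomial error small
enough that a 3-SE band is meaningful), 200 random small tables for the
brute-force ROR cross-check, 50 random fixtures for the two independent
LOOCV oracles (refit loop and leverage identity, both at $10^{-10}$), 100
Monte-Carlo replicates for noisy coefficient recovery at a cancer-level noise
SD of 0.15 (kept well below the planted ROR floor so every replicate is a
valid configuration), and 200 replicates × 1000 features for the global-null
BH calibration.

## Known limitations

* The default irAE term list is a documented synthetic placeholder; the
  curated preferred-term list of any real analysis is a required, versioned
  input.
* The 2×2 comparator is "other cancer types within the monotherapy stratum";
  comparing against all other reports in the full database is possible by
  passing an explicit `comparator` table, but the two designs answer
  different questions.
* Only plain Pearson screening and unregularized OLS are implemented — no
  rank correlations, interaction terms, or shrinkage; the six-variable
  combined model is handled by the same enumeration machinery, not
  special-cased.
* Validation-cohort analyses report nominal p-values per gene (a configurable
  BH adjustment is available) and do not model irAE subtypes or time-to-event
  structure.

## A minimal run

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 7, out_dir = tempfile("irae_"),
                         sim = list(reports_per_type = 2000)))
summary(res$ror)       # case counts, irAE percentage, ROR range
head(res$screen)       # correlation screen with per-family FDR
summary(res$search)    # best model per size with LOOCV R and VIF
```
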