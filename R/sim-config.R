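#' Configuration for the synthetic irAE study generator
#'
#' Builds a validated configuration describing the planted structure of a
#' synthetic study: spontaneous adverse-event reports whose per-cancer-type
#' irAE probability is driven by a planted linear model on immunogenomic
#' factor means, a matched patient cohort with omics layers, and an
#' independent validation cohort. A single `seed` fully determines every
#' table; each table draws from its own derived stream so adding an omics
#' layer never perturbs the report table.
#'
#' The planted model is
#' \deqn{ROR_k = intercept + \sum_j \beta_j \, mean_{jk} + \epsilon_k,}
#' with \eqn{\epsilon_k \sim N(0, noise\_sd)}, and the per-type irAE
#' probability in the anti-PD-1 monotherapy stratum is
#' \deqn{p_k = \frac{odds_0 \cdot ROR_k}{1 + odds_0 \cdot ROR_k},}
#' where \eqn{odds_0} is `background_irae_odds`, the irAE odds of a
#' reference stratum with ROR = 1.
#'
#' @param n_cancer_types number of cancer types (default 21, the size of the
#'   pan-cancer factor panel this generator emulates).
#' @param reports_per_type reports per cancer type; scalar or length
#'   `n_cancer_types` vector.
#' @param background_irae_odds odds of an irAE in the reference stratum.
#' @param true_coefficients named numeric vector of planted weights linking
#'   cancer-level factor means to the planted ROR.
#' @param intercept planted intercept of the linear model.
#' @param factor_ranges named list of `c(min, max)` ranges from which the
#'   per-type factor means are drawn. The `log_TMB` range is interpreted on
#'   the log10(count + 1) scale and snapped to exactly representable values
#'   (log10 of an integer + 1) so that zero-dispersion cohorts reproduce the
#'   planted means exactly.
#' @param noise_sd cancer-level residual noise on the planted ROR scale.
#' @param true_irae_prob optional override: per-type irAE probability in
#'   `[0,1]` (scalar or vector), bypassing the planted linear model.
#' @param patients_per_type cohort patients per cancer type.
#' @param within_type_sd within-type SD of per-patient cell-abundance draws.
#' @param tmb_dispersion within-type SD of per-patient log10 mutation counts.
#' @param n_genes,n_mirnas,n_proteins features per omics layer.
#' @param n_hits_per_kind features per layer planted to track the ROR across
#'   types (the rest are null).
#' @param expr_sd within-type SD of per-patient log2 expression.
#' @param irae_term_fraction fraction of the reaction vocabulary that is an
#'   irAE preferred term.
#' @param n_reaction_terms size of the reaction vocabulary.
#' @param drug_mixture probabilities of the three suspected-drug strata
#'   (anti-PD-1 monotherapy, other drug, anti-PD-1 + ipilimumab).
#' @param n_validation_patients validation-cohort size.
#' @param n_validation_genes genes in the validation expression table.
#' @param validation_effect named log2-TPM shifts between irAE-positive and
#'   irAE-negative validation patients for designated genes.
#' @param validation_therapy_mix probabilities of therapy classes in the
#'   validation cohort.
#' @param grade_probs probabilities of worst irAE grades 0..4.
#' @param seed integer seed; identical configs give byte-identical output.
#' @return an object of class `sim_config`.
#' @seealso [simulate_reports()], [simulate_cohort()],
#'   [simulate_validation_cohort()], [expected_ror()]
#' @export
sim_config <- function(n_cancer_types = 21,
                       reports_per_type = 500,
                       background_irae_odds = 0.1,
                       true_coefficients = c(DC = 19.03, log_TMB = 0.82,
                                             naiveCD4T = 18.03),
                       intercept = -1.85,
                       factor_ranges = NULL,
                       noise_sd = 0,
                       true_irae_prob = NULL,
                       patients_per_type = 40,
                       within_type_sd = 0.02,
                       tmb_dispersion = 0.2,
                       n_genes = 120, n_mirnas = 40, n_proteins = 40,
                       n_hits_per_kind = 4,
                       expr_sd = 0.4,
                       irae_term_fraction = 0.3,
                       n_reaction_terms = 40,
                       drug_mixture = c(anti_pd1 = 0.5, other = 0.3,
                                        combination = 0.2),
                       n_validation_patients = 60,
                       n_validation_genes = 20,
                       validation_effect = c(IRF4 = 0.6, TCL1A = 0.4),
                       validation_therapy_mix = c(anti_pd1 = 0.75,
                                                  combination = 0.25),
                       grade_probs = c(0.45, 0.2, 0.15, 0.1, 0.1),
                       seed = 1L) {
  assert_count(n_cancer_types, "n_cancer_types")
  assert_count(reports_per_type, "reports_per_type")
  if (!length(reports_per_type) %in% c(1L, n_cancer_types))
    stop_config("'reports_per_type' must be scalar or length n_cancer_types")
  assert_scalar_number(background_irae_odds, "background_irae_odds",
                       min = .Machine$double.eps)
  if (!is.numeric(true_coefficients) || is.null(names(true_coefficients)) ||
      any(!nzchar(names(true_coefficients))))
    stop_config("'true_coefficients' must be a named numeric vector")
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(true_irae_prob)) {
    if (!is.numeric(true_irae_prob) ||
        !length(true_irae_prob) %in% c(1L, n_cancer_types) ||
        any(true_irae_prob < 0) || any(true_irae_prob > 1))
      stop_config("'true_irae_prob' override must lie in [0,1]")
    true_irae_prob <- rep_len(true_irae_prob, n_cancer_types)
  }
  assert_count(patients_per_type, "patients_per_type")
  assert_scalar_number(within_type_sd, "within_type_sd", min = 0)
  assert_scalar_number(tmb_dispersion, "tmb_dispersion", min = 0)
  assert_count(n_genes, "n_genes", min = 0L)
  assert_count(n_mirnas, "n_mirnas", min = 0L)
  assert_count(n_proteins, "n_proteins", min = 0L)
  assert_count(n_hits_per_kind, "n_hits_per_kind", min = 0L)
  assert_scalar_number(expr_sd, "expr_sd", min = 0)
  assert_scalar_number(irae_term_fraction, "irae_term_fraction", 0, 1)
  assert_count(n_reaction_terms, "n_reaction_terms", min = 2L)
  n_irae_terms <- round(irae_term_fraction * n_reaction_terms)
  if (irae_term_fraction > 0 && irae_term_fraction < 1 &&
      (n_irae_terms < 1 || n_irae_terms > n_reaction_terms - 1))
    stop_config("reaction vocabulary needs >= 1 irAE and >= 1 non-irAE term")
  if (!is.numeric(drug_mixture) || length(drug_mixture) != 3 ||
      any(drug_mixture < 0) || sum(drug_mixture) <= 0)
    stop_config("'drug_mixture' must be 3 nonnegative weights")
  assert_count(n_validation_patients, "n_validation_patients")
  assert_count(n_validation_genes, "n_validation_genes")
  if (length(validation_effect) &&
      (is.null(names(validation_effect)) || !is.numeric(validation_effect)))
    stop_config("'validation_effect' must be a named numeric vector")
  if (!is.numeric(grade_probs) || length(grade_probs) != 5 ||
      any(grade_probs < 0) || sum(grade_probs) <= 0)
    stop_config("'grade_probs' must be 5 nonnegative weights (grades 0..4)")
  assert_count(seed, "seed", min = 0L)

  default_ranges <- list(DC = c(0.08, 0.25), log_TMB = c(1, 3),
                         naiveCD4T = c(0.02, 0.15))
  ranges <- default_ranges
  if (!is.null(factor_ranges)) ranges[names(factor_ranges)] <- factor_ranges
  for (f in names(true_coefficients))
    if (is.null(ranges[[f]])) ranges[[f]] <- c(0, 1)

  cfg <- list(n_cancer_types = as.integer(n_cancer_types),
              reports_per_type = rep_len(as.integer(reports_per_type),
                                         n_cancer_types),
              background_irae_odds = background_irae_odds,
              true_coefficients = true_coefficients,
              intercept = intercept,
              factor_ranges = ranges,
              noise_sd = noise_sd,
              true_irae_prob = true_irae_prob,
              patients_per_type = as.integer(patients_per_type),
              within_type_sd = within_type_sd,
              tmb_dispersion = tmb_dispersion,
              n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_proteins = as.integer(n_proteins),
              n_hits_per_kind = as.integer(n_hits_per_kind),
              expr_sd = expr_sd,
              irae_term_fraction = irae_term_fraction,
              n_reaction_terms = as.integer(n_reaction_terms),
              drug_mixture = drug_mixture / sum(drug_mixture),
              n_validation_patients = as.integer(n_validation_patients),
              n_validation_genes = as.integer(n_validation_genes),
              validation_effect = validation_effect,
              validation_therapy_mix =
                validation_therapy_mix / sum(validation_therapy_mix),
              grade_probs = grade_probs / sum(grade_probs),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic irAE study configuration\n")
  cat(sprintf("  %d cancer types, %s reports/type, %d patients/type\n",
              x$n_cancer_types,
              paste(range(x$reports_per_type), collapse = "-"),
              x$patients_per_type))
  cat(sprintf("  planted model: ROR = %.3g + %s  (noise sd %.3g)\n",
              x$intercept,
              paste(sprintf("%.3g*%s", x$true_coefficients,
                            names(x$true_coefficients)), collapse = " + "),
              x$noise_sd))
  cat(sprintf("  omics: %d genes, %d miRNAs, %d proteins (%d hits each)\n",
              x$n_genes, x$n_mirnas, x$n_proteins, x$n_hits_per_kind))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
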