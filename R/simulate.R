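# Synthetic-data generator: spontaneous-report tables, pan-cancer cohorts
# with omics layers, and a patient-level validation cohort, all with known
# planted structure recorded in a SimTruth object.

DECOY_CELLS <- c("CD8_Tcells", "Mast_cells", "CD4_Tcells", "Bcells",
                 "NK_cells", "Macrophages", "Tregs", "Monocytes")

# Planted ground truth is a pure function of the config (drawn from stream 1),
# so reports and cohort generated separately from the same config share it.
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 1L))
  n <- config$n_cancer_types
  types <- sprintf("CT%02d", seq_len(n))
  factors <- names(config$true_coefficients)

  means <- matrix(NA_real_, n, length(factors),
                  dimnames = list(types, factors))
  tmb_counts <- NULL
  for (f in factors) {
    rg <- config$factor_ranges[[f]]
    if (f == "log_TMB") {
      # snap to log10(integer + 1) so zero-dispersion cohorts hit the mean
      u <- stats::runif(n, rg[1], rg[2])
      tmb_counts <- pmax(1L, as.integer(round(10^u - 1)))
      means[, f] <- log10(tmb_counts + 1)
    } else {
      means[, f] <- stats::runif(n, rg[1], rg[2])
    }
  }
  decoys <- matrix(stats::runif(n * length(DECOY_CELLS), 0.02, 0.30),
                   n, length(DECOY_CELLS),
                   dimnames = list(types, DECOY_CELLS))
  noise <- stats::rnorm(n, 0, config$noise_sd)

  true_ror <- drop(config$intercept + means %*% config$true_coefficients +
                     noise)
  names(true_ror) <- types
  if (is.null(config$true_irae_prob)) {
    if (any(true_ror <= 0))
      stop_config(paste("planted ROR is nonpositive for some cancer type;",
                        "adjust factor_ranges / intercept / noise_sd"))
    odds <- config$background_irae_odds * true_ror
    prob <- odds / (1 + odds)
  } else {
    prob <- config$true_irae_prob
    true_ror <- ifelse(prob <= 0 | prob >= 1, NA_real_,
                       (prob / (1 - prob)) / config$background_irae_odds)
    names(true_ror) <- types
  }
  names(prob) <- types

  n_irae_terms <- round(config$irae_term_fraction * config$n_reaction_terms)
  irae_terms <- if (n_irae_terms > 0)
    sprintf("irae reaction %02d", seq_len(n_irae_terms)) else character(0)
  other_terms <- if (config$n_reaction_terms - n_irae_terms > 0)
    sprintf("other reaction %02d",
            seq_len(config$n_reaction_terms - n_irae_terms)) else character(0)

  # planted screen hits: log2 mean tracks the standardized planted ROR
  ror_z <- if (stats::sd(true_ror) > 0 && !anyNA(true_ror))
    (true_ror - mean(true_ror)) / stats::sd(true_ror) else rep(0, n)
  hit_spec <- function(kind, n_feat) {
    if (n_feat == 0) return(NULL)
    ids <- sprintf("%s_%04d", toupper(kind), seq_len(n_feat))
    n_hit <- min(config$n_hits_per_kind, n_feat)
    list(ids = ids,
         hits = ids[seq_len(n_hit)],
         slope = stats::runif(n_feat, 0.8, 1.5) *
           c(rep(1, n_hit), rep(0, n_feat - n_hit)),
         base = stats::runif(n_feat, 2, 6))
  }
  features <- list(mrna = hit_spec("gene", config$n_genes),
                   mirna = hit_spec("mir", config$n_mirnas),
                   protein = hit_spec("prot", config$n_proteins))

  structure(list(cancer_types = types,
                 true_ror = true_ror,
                 true_irae_prob = prob,
                 planted_factor_means = means,
                 decoy_cell_means = decoys,
                 true_coefficients = config$true_coefficients,
                 intercept = config$intercept,
                 background_irae_odds = config$background_irae_odds,
                 noise = noise,
                 tmb_counts = tmb_counts,
                 ror_z = ror_z,
                 features = features,
                 irae_terms = irae_terms,
                 other_terms = other_terms),
            class = "sim_truth")
}

#' Exact pooled-background reporting odds ratio implied by planted probabilities
#'
#' The generator plants per-type irAE probabilities against an explicit
#' reference stratum, but a disproportionality analysis compares each type to
#' the *pooled* other types, whose irAE rate depends on all strata. This
#' oracle computes the exact ROR implied by the planted probabilities under
#' that pooled comparator, so convergence tests compare estimates against the
#' exact implied value rather than the nominal planted one.
#'
#' @param probs per-type irAE probabilities (named or not).
#' @param weights per-type report weights (e.g. reports per type); defaults
#'   to equal weights.
#' @return numeric vector of implied RORs, one per type.
#' @export
expected_ror <- function(probs, weights = NULL) {
  if (!is.numeric(probs) || any(probs <= 0) || any(probs >= 1))
    stop_input("'probs' must lie strictly in (0,1)")
  if (is.null(weights)) weights <- rep(1, length(probs))
  if (length(weights) != length(probs) || any(weights <= 0))
    stop_input("'weights' must be positive and match 'probs' in length")
  odds <- probs / (1 - probs)
  out <- vapply(seq_along(probs), function(k) {
    w <- weights[-k]
    p_other <- sum(w * probs[-k]) / sum(w)
    odds[k] / (p_other / (1 - p_other))
  }, numeric(1))
  names(out) <- names(probs)
  out
}

#' Simulate a spontaneous adverse-event report table
#'
#' Emulates a pharmacovigilance extract: one row per report with suspected
#' drugs, a cancer-type indication, and a semicolon-delimited list of reaction
#' preferred terms. Anti-PD-1 monotherapy reports in cancer type k carry at
#' least one irAE term with the planted probability `true_irae_prob[k]`;
#' other-drug and combination reports carry irAE terms at the background
#' reference rate (they are excluded by the monotherapy filter downstream).
#'
#' @param config a [sim_config()] object.
#' @return list with elements `reports` (data.frame: report_id, drugs,
#'   indication, reactions; multi-valued fields semicolon-delimited) and
#'   `truth` (the planted `sim_truth`).
#' @export
simulate_reports <- function(config) {
  truth <- sim_truth(config)
  if (length(truth$irae_terms) == 0 && any(truth$true_irae_prob > 0))
    stop_config("no irAE terms in vocabulary but planted probability > 0")
  set.seed(stream_seed(config$seed, 2L))

  n_total <- sum(config$reports_per_type)
  indication <- rep(truth$cancer_types, config$reports_per_type)
  stratum <- sample(c("anti_pd1", "other", "combination"), n_total,
                    replace = TRUE, prob = config$drug_mixture)
  p0 <- config$background_irae_odds / (1 + config$background_irae_odds)
  p <- ifelse(stratum == "anti_pd1",
              truth$true_irae_prob[indication], p0)
  if (length(truth$other_terms) == 0 && any(p < 1))
    stop_config(paste("vocabulary has no non-irAE term but some reports",
                      "must be irAE-free; lower irae_term_fraction"))
  has_irae <- stats::runif(n_total) < p

  pd1_agents <- c("nivolumab", "pembrolizumab")
  other_agents <- c("carboplatin", "paclitaxel", "sorafenib")
  drugs <- character(n_total)
  agent <- sample(pd1_agents, n_total, replace = TRUE)
  drugs[stratum == "anti_pd1"] <- agent[stratum == "anti_pd1"]
  drugs[stratum == "combination"] <-
    paste(agent[stratum == "combination"], "ipilimumab", sep = ";")
  drugs[stratum == "other"] <- sample(other_agents, sum(stratum == "other"),
                                      replace = TRUE)

  # vectorized reaction sampling: each report gets 1-2 distinct terms from
  # its primary vocabulary plus at most one extra from the other vocabulary
  n_ir <- length(truth$irae_terms)
  n_ot <- length(truth$other_terms)
  draw_pair <- function(vocab, n) {
    m <- length(vocab)
    i1 <- sample.int(m, n, replace = TRUE)
    two <- m > 1 & stats::runif(n) < 0.5
    i2 <- if (m > 1)
      (i1 + sample.int(m - 1, n, replace = TRUE) - 1L) %% m + 1L else i1
    ifelse(two, paste(vocab[i1], vocab[i2], sep = ";"), vocab[i1])
  }
  reactions <- character(n_total)
  if (any(has_irae)) {
    k <- sum(has_irae)
    main <- draw_pair(truth$irae_terms, k)
    extra <- if (n_ot > 0) {
      add <- stats::runif(k) < 0.5
      idx <- sample.int(n_ot, k, replace = TRUE)
      ifelse(add, paste0(";", truth$other_terms[idx]), "")
    } else ""
    reactions[has_irae] <- paste0(main, extra)
  }
  if (any(!has_irae))
    reactions[!has_irae] <- draw_pair(truth$other_terms, sum(!has_irae))

  reports <- data.frame(report_id = sprintf("R%07d", seq_len(n_total)),
                        drugs = drugs,
                        indication = indication,
                        reactions = reactions,
                        stringsAsFactors = FALSE)
  list(reports = reports, truth = truth)
}

#' Simulate a pan-cancer patient cohort with omics layers
#'
#' Per-cancer-type factor means are planted so that
#' `intercept + sum(beta_j * mean_jk) + noise_k` equals the planted ROR of
#' type k; per-patient values are drawn around those means. Expression
#' matrices (features x patients) are log-normal-like; a planted subset of
#' features tracks the ROR across types via cancer-level mean shifts, the
#' rest are null.
#'
#' @param config a [sim_config()] object.
#' @return list with `patients` (data.frame: patient_id, cancer_type,
#'   nonsynonymous_mutation_count, one column per cell type), `omics`
#'   (named list of feature-by-patient matrices: mrna, mirna, protein) and
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  truth <- sim_truth(config)
  set.seed(stream_seed(config$seed, 3L))
  n <- config$n_cancer_types
  m <- config$patients_per_type
  types <- rep(truth$cancer_types, each = m)
  ids <- sprintf("P%05d", seq_along(types))

  if (is.null(truth$tmb_counts))
    stop_config("cohort simulation requires a 'log_TMB' planted factor")
  log_mean <- log10(truth$tmb_counts + 1)[match(types, truth$cancer_types)]
  counts <- if (config$tmb_dispersion == 0) {
    truth$tmb_counts[match(types, truth$cancer_types)]
  } else {
    pmax(0L, as.integer(round(
      10^(log_mean + stats::rnorm(length(types), 0, config$tmb_dispersion)) - 1)))
  }

  cell_means <- cbind(
    truth$planted_factor_means[, setdiff(colnames(truth$planted_factor_means),
                                         "log_TMB"), drop = FALSE],
    truth$decoy_cell_means)
  cells <- apply(cell_means, 2, function(mu) {
    v <- mu[match(types, truth$cancer_types)]
    if (config$within_type_sd > 0)
      v <- v + stats::rnorm(length(v), 0, config$within_type_sd)
    pmin(1, pmax(0, v))
  })

  patients <- data.frame(patient_id = ids, cancer_type = types,
                         nonsynonymous_mutation_count = counts,
                         stringsAsFactors = FALSE)
  patients <- cbind(patients, as.data.frame(cells))

  type_idx <- match(types, truth$cancer_types)
  gen_kind <- function(spec, stream) {
    if (is.null(spec)) return(NULL)
    set.seed(stream_seed(config$seed, stream))
    mu <- outer(spec$base, rep(1, n)) +
      outer(spec$slope, truth$ror_z)          # features x types, log2 scale
    lv <- mu[, type_idx, drop = FALSE]
    if (config$expr_sd > 0)
      lv <- lv + matrix(stats::rnorm(length(lv), 0, config$expr_sd),
                        nrow(lv), ncol(lv))
    vals <- 2^lv - 1
    vals[vals < 0] <- 0
    dimnames(vals) <- list(spec$ids, ids)
    vals
  }
  omics <- list(mrna = gen_kind(truth$features$mrna, 4L),
                mirna = gen_kind(truth$features$mirna, 5L),
                protein = gen_kind(truth$features$protein, 6L))
  omics <- omics[!vapply(omics, is.null, logical(1))]

  list(patients = patients, omics = omics, truth = truth)
}

#' Simulate an independent validation cohort
#'
#' Emulates a patient-level immune-checkpoint-inhibitor cohort: therapy class
#' (anti-PD-1 monotherapy or anti-PD-1 + ipilimumab combination), worst irAE
#' grade 0-4, and gene expression in TPM. Genes named in
#' `config$validation_effect` are shifted (on the log2-TPM scale) between
#' irAE-positive (grade >= 1) and irAE-negative patients; all other genes are
#' null.
#'
#' @param config a [sim_config()] object.
#' @return data.frame: patient_id, therapy_class, irae_grade, one column per
#'   gene (TPM).
#' @export
simulate_validation_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 7L))
  n <- config$n_validation_patients
  therapy <- sample(c("anti-PD-1", "combination"), n, replace = TRUE,
                    prob = config$validation_therapy_mix)
  grade <- sample(0:4, n, replace = TRUE, prob = config$grade_probs)
  irae <- as.numeric(grade >= 1)

  eff_genes <- names(config$validation_effect)
  n_null <- max(0L, config$n_validation_genes - length(eff_genes))
  genes <- c(eff_genes, if (n_null > 0) sprintf("NULLG_%03d", seq_len(n_null)))
  expr <- sapply(genes, function(g) {
    base <- stats::runif(1, 1, 4)
    shift <- if (g %in% eff_genes) config$validation_effect[[g]] else 0
    lv <- base + shift * irae + stats::rnorm(n, 0, 0.5)
    pmax(0, 2^lv - 1)
  })
  out <- data.frame(patient_id = sprintf("V%04d", seq_len(n)),
                    therapy_class = therapy,
                    irae_grade = as.integer(grade),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(expr))
}
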