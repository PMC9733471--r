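# End-to-end orchestration: simulate (optional) -> ROR -> factor medians ->
# correlation screen -> model search (-> external prediction) -> cohort
# validation, with per-stage TSV outputs and a machine-readable run summary.

#' Default pipeline configuration
#'
#' All thresholds of the analysis surfaced in one place; any entry can be
#' overridden via the `config` list / YAML file passed to [run_pipeline()].
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(seed = 1L,
       out_dir = "irae_screen_out",
       simulate = TRUE,              # generate inputs from sim (below)
       sim = list(),                 # overrides passed to sim_config()
       reports_file = NULL, terms_file = NULL,
       patients_file = NULL, mrna_file = NULL, mirna_file = NULL,
       protein_file = NULL, gmt_file = NULL,
       cohort_meta_file = NULL, cohort_expr_file = NULL,
       target_drugs = c("nivolumab", "pembrolizumab"),
       excluded_cotreatments = "ipilimumab",
       fdr_alpha = 0.05,
       vif_limit = 4,
       lr_alpha = 0.05,
       pd1_percentile = 80,
       grade_cut = 1,
       model_sizes = 1:3,
       candidates = NULL,            # NULL = panel factors
       validation_genes = NULL,      # NULL = all genes in the cohort
       stages = c("ror", "features", "correlate", "modelsearch", "validate"))
}

apply_config <- function(base, override) {
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

#' Run the irAE risk screening pipeline
#'
#' Executes the toggled stages in order on supplied files or on synthetic
#' data with planted structure, writes one TSV per stage plus a JSON run
#' summary into `out_dir`, and returns the stage results invisibly. Identical
#' config and inputs give identical outputs.
#'
#' @param config named list of overrides to [pipeline_defaults()], or a path
#'   to a YAML file with the same structure.
#' @return (invisibly) list with elements `ror`, `factor_matrix`, `screen`,
#'   `search`, `validation`, `summary`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- apply_config(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, msg)
    message(sprintf("[irae-screen] %6.1fs %-11s %s",
                    proc.time()[["elapsed"]] - t0, stage, msg))
  results <- list()

  # --- inputs -------------------------------------------------------------
  terms <- NULL
  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    sc <- do.call(sim_config, apply_config(list(seed = cfg$seed), cfg$sim))
    simr <- simulate_reports(sc)
    reports <- simr$reports
    terms <- irae_terms(simr$truth$irae_terms)
    sim <- simulate_cohort(sc)
    patients <- sim$patients
    omics <- sim$omics
    cohort <- simulate_validation_cohort(sc)
    signatures <- list()
    log_stage("simulate", sprintf("%d reports, %d patients, %d cancer types",
                                  nrow(reports), nrow(patients),
                                  sc$n_cancer_types))
  } else {
    reports <- if (!is.null(cfg$reports_file)) read_reports(cfg$reports_file)
    terms <- if (!is.null(cfg$terms_file)) read_irae_terms(cfg$terms_file)
    patients <- if (!is.null(cfg$patients_file)) read_tsv(cfg$patients_file)
    omics <- list()
    for (kind in c("mrna", "mirna", "protein")) {
      f <- cfg[[paste0(kind, "_file")]]
      if (!is.null(f)) omics[[kind]] <- read_expression(f)
    }
    signatures <- if (!is.null(cfg$gmt_file)) read_gmt(cfg$gmt_file) else list()
    cohort <- if (!is.null(cfg$cohort_meta_file))
      read_cohort(cfg$cohort_meta_file, cfg$cohort_expr_file)
  }

  # --- ror ----------------------------------------------------------------
  ror <- NULL
  if ("ror" %in% cfg$stages) {
    if (is.null(reports) || is.null(terms))
      stop_input("stage 'ror' needs reports and an irAE term list")
    mono <- filter_monotherapy(reports, cfg$target_drugs,
                               cfg$excluded_cotreatments)
    ror <- ror_by_cancer(mono, terms)
    write_tsv(as.data.frame(ror), file.path(cfg$out_dir, "ror.tsv"))
    results$ror <- ror
    log_stage("ror", sprintf("%d types; %d/%d (%.2f%%) cases with irAE",
                             nrow(ror), attr(ror, "n_irae_total"),
                             attr(ror, "n_total"),
                             percent_irae(attr(ror, "n_irae_total"),
                                          attr(ror, "n_total"))))
  }

  # --- features -----------------------------------------------------------
  fm <- NULL
  if ("features" %in% cfg$stages) {
    if (is.null(patients)) stop_input("stage 'features' needs a patient table")
    if (is.null(ror)) stop_input("stage 'features' needs the 'ror' stage output")
    fm <- median_factor_matrix(patients, omics, signatures, ror,
                               pd1_percentile = cfg$pd1_percentile)
    write_factor_matrix(fm, file.path(cfg$out_dir, "factor_matrix.tsv"))
    results$factor_matrix <- fm
    log_stage("features", sprintf("%d types x %d factors",
                                  nrow(fm$values), ncol(fm$values)))
  }

  # --- correlate ----------------------------------------------------------
  if ("correlate" %in% cfg$stages) {
    if (is.null(fm)) stop_input("stage 'correlate' needs the 'features' output")
    scr <- screen_factors(fm, alpha = cfg$fdr_alpha)
    write_tsv(as.data.frame(scr), file.path(cfg$out_dir, "screen.tsv"))
    results$screen <- scr
    log_stage("correlate", sprintf("%d factors, %d significant",
                                   nrow(scr), sum(scr$significant)))
  }

  # --- modelsearch --------------------------------------------------------
  if ("modelsearch" %in% cfg$stages) {
    if (is.null(fm)) stop_input("stage 'modelsearch' needs the 'features' output")
    search <- search_ror_models(fm, candidates = cfg$candidates,
                                sizes = cfg$model_sizes,
                                vif_limit = cfg$vif_limit,
                                lr_alpha = cfg$lr_alpha)
    write_tsv(search$table, file.path(cfg$out_dir, "models.tsv"))
    results$search <- search
    log_stage("modelsearch", sprintf("%d models; best LOOCV R = %.3f [%s]",
                                     nrow(search$table),
                                     search$table$loocv_r[1],
                                     search$table$model[1]))
  }

  # --- validate -----------------------------------------------------------
  if ("validate" %in% cfg$stages) {
    if (is.null(cohort)) stop_input("stage 'validate' needs a cohort table")
    genes <- cfg$validation_genes
    if (is.null(genes))
      genes <- setdiff(names(cohort),
                       c("patient_id", "therapy_class", "irae_grade"))
    val <- do.call(rbind, lapply(genes, function(g) {
      ia <- irae_association(cohort, g, grade_cut = cfg$grade_cut)
      adj <- tryCatch(adjusted_association(cohort, g, cfg$grade_cut),
                      irae_degenerate_error = function(e) NULL)
      data.frame(gene = g, median_irae = ia$median_irae,
                 median_no_irae = ia$median_no_irae, U = ia$U, p = ia$p,
                 adj_coefficient = if (is.null(adj)) NA_real_ else adj$coefficient,
                 adj_p = if (is.null(adj)) NA_real_ else adj$p)
    }))
    write_tsv(val, file.path(cfg$out_dir, "validation.tsv"))
    results$validation <- val
    log_stage("validate", sprintf("%d genes tested", nrow(val)))
  }

  # --- summary ------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  run_summary <- list(
    package_version = as.character(utils::packageVersion("iraescreen")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tf)),
    thresholds = cfg[c("fdr_alpha", "vif_limit", "lr_alpha",
                       "pd1_percentile", "grade_cut")],
    stages_run = cfg$stages)
  unlink(tf)
  if (!is.null(results$ror))
    run_summary$ror <- list(n_types = nrow(results$ror),
                        n_cases = attr(results$ror, "n_total"),
                        n_irae = attr(results$ror, "n_irae_total"),
                        percent_irae = percent_irae(
                          attr(results$ror, "n_irae_total"),
                          attr(results$ror, "n_total")))
  if (!is.null(results$screen)) {
    top <- results$screen[order(-abs(results$screen$r)), ]
    run_summary$screen <- list(n_factors = nrow(top),
                           n_significant = sum(top$significant),
                           top_factors = utils::head(top$factor, 5))
  }
  if (!is.null(results$search)) {
    bb <- summary(results$search)$best_by_size
    run_summary$models <- list(n_models = nrow(results$search$table),
                           best_by_size = bb[, c("model", "size", "loocv_r",
                                                 "fdr", "admissible")])
  }
  jsonlite::write_json(run_summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$summary <- run_summary
  log_stage("done", sprintf("outputs in %s", cfg$out_dir))
  invisible(results)
}
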