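test_that("TMB transform follows the log10(count + 1) convention", {
  expect_equal(compute_tmb(c(0, 99, 999)), c(0, 2, 3))
  expect_equal(compute_tmb(7, base = 2, offset = 1), 3)
  expect_error(compute_tmb(-1), class = "irae_input_error")
  # strictly increasing
  x <- compute_tmb(0:50)
  expect_true(all(diff(x) > 0))
})

test_that("signature scoring follows the two stated conventions", {
  expr <- rbind(g1 = c(4, 1), g2 = c(9, 3))
  colnames(expr) <- c("p1", "p2")
  gm <- signature_score(expr, c("g1", "g2"), "geometric_mean", eps = 0)
  expect_equal(unname(gm["p1"]), 6)
  ml <- signature_score(expr, c("g1", "g2"), "mean_log")["p2"]
  expect_equal(unname(ml), (log2(2) + log2(4)) / 2)  # 1.5
  # single-gene set reduces to that gene's transformed value
  one <- signature_score(expr, "g1", "mean_log")
  expect_equal(unname(one), log2(expr["g1", ] + 1), ignore_attr = TRUE)
  expect_warning(signature_score(expr, c("g1", "absent"), "mean_log"),
                 "missing")
  expect_error(signature_score(expr, "absent", "mean_log"),
               class = "irae_input_error")
})

test_that("PD-1-high proportion uses the pooled interpolated cutoff", {
  expr <- matrix(1:10, nrow = 1, dimnames = list("PDCD1", paste0("p", 1:10)))
  ct <- rep(c("A", "B"), c(4, 6))
  # pooled 80th percentile of 1..10 (type-7 quantile) is 8.2
  expr["PDCD1", ] <- c(9, 10, 1, 2, 3, 4, 5, 6, 7, 8)
  pr <- pd1_high_proportion(expr, ct, percentile = 80)
  expect_equal(unname(pr["A"]), 0.5)   # {9,10,1,2}: two strictly above 8.2
  expect_equal(unname(pr["B"]), 0)
  # all-equal cohort: nothing strictly above the cutoff
  expr["PDCD1", ] <- 5
  expect_equal(unname(pd1_high_proportion(expr, ct)), c(0, 0))
  expect_error(pd1_high_proportion(expr, ct, gene_id = "CD274"),
               class = "irae_input_error")
})

test_that("pooled PD-1-high fraction respects the percentile bound", {
  set.seed(4)
  expr <- matrix(rlnorm(500), nrow = 1, dimnames = list("PDCD1", NULL))
  colnames(expr) <- paste0("p", 1:500)
  ct <- sample(LETTERS[1:5], 500, replace = TRUE)
  pr <- pd1_high_proportion(expr, ct)
  expect_true(all(pr >= 0 & pr <= 1))
  global <- mean(expr["PDCD1", ] > quantile(expr["PDCD1", ], 0.8))
  expect_lte(global, 0.2 + 1 / 500)
})

test_that("preprocessing log2-transforms and drops zero-median features", {
  expr <- rbind(allzero = rep(0, 6),
                mostlyzero = c(0, 0, 0, 0, 5, 5),
                keep = c(7, 7, 7, 7, 7, 7))
  colnames(expr) <- paste0("p", 1:6)
  ct <- rep(c("A", "B", "C"), each = 2)
  out <- preprocess_expression(expr, ct)
  expect_identical(rownames(out), "keep")      # zero median in 2/3 types
  expect_equal(unname(out["keep", 1]), 3)      # log2(8)
  # no zero-median features: dimensionality preserved
  full <- preprocess_expression(expr["keep", , drop = FALSE] + 1, ct)
  expect_identical(dim(full), c(1L, 6L))
  expect_error(preprocess_expression(expr["allzero", , drop = FALSE], ct),
               class = "irae_degenerate_error")
})

test_that("median aggregation uses midpoint convention and aligns the outcome", {
  patients <- data.frame(
    patient_id = sprintf("p%02d", 1:12),
    cancer_type = rep(c("A", "B", "C"), each = 4),
    nonsynonymous_mutation_count = rep(c(9, 99, 999), each = 4),
    DC = c(1, 2, 3, 4,  2, 2, 2, 2,  0, 1, 1, 0) / 10)
  ror <- data.frame(cancer_type = c("A", "B", "C"), ror = c(1.5, 2, 3))
  fm <- median_factor_matrix(patients, ror = ror)
  expect_s3_class(fm, "factor_matrix")
  expect_equal(fm$values["A", "DC"], 0.25)     # even group -> midpoint
  expect_equal(fm$values["A", "log_TMB"], 1)
  expect_equal(unname(fm$outcome), c(1.5, 2, 3))
  # permutation invariance over patients
  fm2 <- median_factor_matrix(patients[sample(12), ], ror = ror)
  expect_equal(fm2$values, fm$values)
  # median robustness: one extreme value does not move an odd-sized median
  p2 <- patients[patients$cancer_type != "A", ]
  p3 <- rbind(p2, within(patients[1, ], DC <- 99))
  fm3 <- median_factor_matrix(p3, ror = ror)
  expect_equal(fm3$values["B", "DC"], 0.2)
})

test_that("cancer types missing from either side are dropped with a warning", {
  patients <- data.frame(patient_id = sprintf("p%02d", 1:8),
                         cancer_type = rep(c("A", "B", "C", "D"), each = 2),
                         nonsynonymous_mutation_count = 10,
                         DC = runif(8))
  ror <- data.frame(cancer_type = c("A", "B", "C", "E"), ror = 1:4)
  expect_warning(fm <- median_factor_matrix(patients, ror = ror), "dropping")
  expect_setequal(rownames(fm$values), c("A", "B", "C"))
  ror2 <- data.frame(cancer_type = c("A", "B"), ror = 1:2)
  expect_error(suppressWarnings(median_factor_matrix(patients, ror = ror2)),
               class = "irae_degenerate_error")
})

test_that("zero-spread simulated cohorts yield medians equal to planted means", {
  cfg <- sim_config(seed = 31, n_cancer_types = 7, patients_per_type = 5,
                    within_type_sd = 0, tmb_dispersion = 0, noise_sd = 0,
                    n_genes = 0, n_mirnas = 0, n_proteins = 0)
  sim <- simulate_cohort(cfg)
  ror <- data.frame(cancer_type = sim$truth$cancer_types,
                    ror = as.numeric(sim$truth$true_ror))
  fm <- median_factor_matrix(sim$patients, ror = ror)
  for (f in c("DC", "naiveCD4T", "log_TMB"))
    expect_equal(fm$values[sim$truth$cancer_types, f],
                 unname(sim$truth$planted_factor_means[, f]))
})

test_that("omics features enter the matrix with their kind as family", {
  cfg <- sim_config(seed = 8, n_cancer_types = 5, patients_per_type = 6,
                    n_genes = 10, n_mirnas = 4, n_proteins = 3)
  sim <- simulate_cohort(cfg)
  ror <- data.frame(cancer_type = sim$truth$cancer_types,
                    ror = as.numeric(sim$truth$true_ror))
  fm <- median_factor_matrix(sim$patients, sim$omics, ror = ror)
  expect_setequal(unique(unname(fm$family)),
                  c("panel", "mrna", "mirna", "protein"))
  expect_true(all(sim$truth$features$mirna$ids %in% colnames(fm$values)))
})

test_that("GMT files parse names, scoring hints, and gene sets", {
  path <- system.file("extdata", "signatures.gmt", package = "iraescreen")
  sets <- iraescreen:::read_gmt(path)
  expect_named(sets, c("cytolytic_index", "ifng_signature",
                       "expanded_immune_signature", "cd8_exhaustion_signature"))
  expect_identical(sets$cytolytic_index$scoring, "geometric_mean")
  expect_setequal(sets$cytolytic_index$genes, c("GZMA", "PRF1"))
  expect_identical(sets$ifng_signature$scoring, "mean_log")
})
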