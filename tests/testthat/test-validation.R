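test_that("Mann-Whitney U and exact p match the enumeration oracle", {
  out <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)   # 2/20 labelings as extreme, two-sided
  expect_true(out$exact)
  # all group sizes with n1 * n2 <= 36, tie-free random values
  set.seed(99)
  for (n1 in 1:6) for (n2 in 1:6) {
    if (n1 * n2 > 36) next
    a <- sample(seq(1, 100, by = 2), n1)   # odd values
    b <- sample(seq(2, 100, by = 2), n2)   # even values -> no ties
    mine <- mann_whitney(a, b)
    oracle <- oracle_mw_exact(a, b)
    expect_equal(mine$U, oracle$U)
    expect_equal(mine$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("U statistics of the two orientations sum to n1 * n2", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(sample(2:15, 1))
    b <- rnorm(sample(2:15, 1))
    ua <- mann_whitney(a, b)$U
    ub <- mann_whitney(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("identical multisets sit at the null center with p near 1", {
  a <- c(1, 2, 3, 4)
  out <- mann_whitney(a, a)
  expect_equal(out$U, length(a)^2 / 2)
  expect_gt(out$p, 0.9)
  expect_false(out$exact)  # ties force the corrected normal approximation
  expect_error(mann_whitney(numeric(0), a), class = "irae_degenerate_error")
})

test_that("brute-force pairwise counting reproduces U on random inputs", {
  set.seed(5)
  for (i in 1:15) {
    a <- sample(1:20, sample(3:8, 1), replace = TRUE)  # ties allowed
    b <- sample(1:20, sample(3:8, 1), replace = TRUE)
    u_pairs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney(a, b)$U, u_pairs)
  }
})

make_cohort <- function(expr_pos, expr_neg, gene = "IRF4",
                        therapy = NULL, grades_pos = NULL) {
  n1 <- length(expr_pos); n0 <- length(expr_neg)
  grade <- c(if (is.null(grades_pos)) rep(1L, n1) else grades_pos,
             rep(0L, n0))
  df <- data.frame(patient_id = sprintf("v%03d", seq_len(n1 + n0)),
                   therapy_class = if (is.null(therapy))
                     rep("anti-PD-1", n1 + n0) else therapy,
                   irae_grade = grade)
  df[[gene]] <- c(expr_pos, expr_neg)
  df
}

test_that("irAE association reports group medians and the Mann-Whitney test", {
  # groups constructed with medians 4.36 (irAE) vs 3.98 (no irAE)
  pos <- c(4.30, 4.36, 5.10)
  neg <- c(3.90, 3.98, 4.05)
  co <- make_cohort(pos, neg)
  out <- irae_association(co, "IRF4")
  expect_equal(out$median_irae, 4.36)
  expect_equal(out$median_no_irae, 3.98)
  expect_equal(out$U, mann_whitney(pos, neg)$U)
  # median robustness to one extreme outlier
  co2 <- make_cohort(c(pos, 400), neg, grades_pos = c(1L, 1L, 1L, 4L))
  out2 <- irae_association(co2, "IRF4")
  expect_equal(out2$median_irae, median(c(pos, 400)))
  expect_equal(out2$median_no_irae, 3.98)
  # degenerate grouping
  co3 <- make_cohort(pos, neg)
  co3$irae_grade <- 0L
  expect_error(irae_association(co3, "IRF4"), class = "irae_degenerate_error")
})

test_that("null gene expression gives calibrated Mann-Whitney p-values", {
  ps <- vapply(1:60, function(i) {
    cfg <- sim_config(seed = 3000 + i, n_validation_patients = 40,
                      validation_effect = c(NULLEFF = 0),
                      n_validation_genes = 1)
    co <- simulate_validation_cohort(cfg)
    irae_association(co, "NULLEFF")$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("therapy-adjusted logistic association behaves at symmetry", {
  # expression symmetric across outcomes: coefficient 0, p = 1
  co <- make_cohort(c(0, 1), c(0, 1), gene = "G")
  out <- adjusted_association(co, "G")
  expect_equal(out$coefficient, 0, tolerance = 1e-8)
  expect_equal(out$p, 1, tolerance = 1e-6)
  # constant outcome is degenerate
  co0 <- make_cohort(c(0, 1), numeric(0), gene = "G")
  expect_error(adjusted_association(co0, "G"),
               class = "irae_degenerate_error")
})

test_that("the logistic slope is recovered within 3 SE on planted data", {
  set.seed(77)
  n <- 2000
  x <- runif(n, 0, 3)   # TPM-like nonnegative expression
  therapy <- sample(c("anti-PD-1", "combination"), n, replace = TRUE)
  eta <- -0.3 + 1.0 * x + 0.5 * (therapy == "combination")
  y <- rbinom(n, 1, plogis(eta))
  co <- data.frame(patient_id = sprintf("p%04d", 1:n),
                   therapy_class = therapy,
                   irae_grade = as.integer(y), G = x)
  out <- adjusted_association(co, "G")
  expect_lt(abs(out$coefficient - 1.0), 3 * out$se)
  expect_lt(out$p, 1e-10)
})

test_that("logistic MLE matches the closed-form 2x2 log odds ratio", {
  # binary expression, one therapy class: MLE slope = log OR of the 2x2 table
  co <- make_cohort(c(rep(1, 30), rep(0, 10)), c(rep(1, 12), rep(0, 28)),
                    gene = "G")
  out <- adjusted_association(co, "G")
  expect_equal(out$coefficient, log((30 * 28) / (10 * 12)), tolerance = 1e-8)
})

test_that("relabeling therapy classes leaves the expression slope unchanged", {
  set.seed(21)
  n <- 120
  co <- data.frame(patient_id = sprintf("p%03d", 1:n),
                   therapy_class = sample(c("anti-PD-1", "combination"), n,
                                          replace = TRUE),
                   irae_grade = rbinom(n, 1, 0.4), G = runif(n, 0, 5))
  a <- adjusted_association(co, "G")
  co$therapy_class <- ifelse(co$therapy_class == "anti-PD-1",
                             "combination", "anti-PD-1")
  b <- adjusted_association(co, "G")
  expect_equal(a$coefficient, b$coefficient, tolerance = 1e-8)
  expect_equal(a$therapy_coefficient, -b$therapy_coefficient,
               tolerance = 1e-8)
})

test_that("complete separation is reported as a diagnostic error", {
  co <- make_cohort(c(5, 6, 7, 8), c(1, 2, 3, 4), gene = "G")
  expect_error(adjusted_association(co, "G"),
               class = "irae_degenerate_error")
})

test_that("grade-wise comparisons test each grade against the reference", {
  # groups constructed with medians 4.7 / 1.61 / 1.32 / 0.81 (grades 4/3/1/0)
  vals <- list(`0` = c(0.70, 0.75, 0.81, 0.90, 0.95),
               `1` = c(1.20, 1.25, 1.32, 1.40, 1.45),
               `3` = c(1.50, 1.55, 1.61, 1.70, 1.75),
               `4` = c(4.60, 4.65, 4.70, 4.85, 4.90))
  co <- data.frame(patient_id = sprintf("g%02d", 1:20),
                   therapy_class = "anti-PD-1",
                   irae_grade = rep(c(0L, 1L, 3L, 4L), each = 5),
                   TCL1A = unlist(vals, use.names = FALSE))
  out <- grade_comparisons(co, "TCL1A", reference_grade = 4)
  expect_equal(out$median[match(c(4, 3, 1, 0), out$grade)],
               c(4.7, 1.61, 1.32, 0.81))
  # reference row carries no self-comparison
  expect_true(is.na(out$p[out$grade == 4]))
  expect_true(all(out$p[out$grade != 4] < 0.05))
  # two-grade cohort: a single comparison
  co2 <- co[co$irae_grade %in% c(0, 4), ]
  out2 <- grade_comparisons(co2, "TCL1A", reference_grade = 4)
  expect_equal(sum(!is.na(out2$p)), 1)
  expect_error(grade_comparisons(co[co$irae_grade == 4, ], "TCL1A"),
               class = "irae_degenerate_error")
  expect_error(grade_comparisons(co, "TCL1A", reference_grade = 2),
               class = "irae_input_error")
})
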