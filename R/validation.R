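# Independent-cohort validation: Mann-Whitney comparisons of gene expression
# by irAE status and grade, and therapy-class-adjusted logistic association.

#' Mann-Whitney U test
#'
#' U for group A counts, over all cross-group pairs, the times an A value
#' exceeds a B value (ties counting one half). The two-sided p-value is exact
#' (full permutation distribution) when `n1 * n2 <= exact_limit` and there
#' are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @param exact_limit use the exact distribution when `n1 * n2` is at most
#'   this and no ties are present (default 400).
#' @return list: `U` (for group A), `p`, `exact` flag, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 400) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop_degenerate("both groups must be nonempty")
  if (!is.numeric(group_a) || !is.numeric(group_b) ||
      anyNA(group_a) || anyNA(group_b))
    stop_input("groups must be numeric without missing values")
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n1 * n2 <= exact_limit) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact,
       n1 = n1, n2 = n2)
}

validate_cohort <- function(cohort, gene = NULL) {
  req <- c("patient_id", "therapy_class", "irae_grade")
  if (!is.data.frame(cohort) || !all(req %in% names(cohort)))
    stop_input("cohort needs columns: %s", paste(req, collapse = ", "))
  g <- cohort$irae_grade
  if (!is.numeric(g) || any(is.na(g)) || any(g < 0 | g > 4 | g != floor(g)))
    stop_input("irae_grade must be integers in 0..4")
  if (!is.null(gene)) {
    if (!gene %in% names(cohort))
      stop_input("gene '%s' absent from the cohort table", gene)
    if (any(cohort[[gene]] < 0, na.rm = TRUE))
      stop_input("TPM values must be nonnegative")
  }
  invisible(cohort)
}

#' Gene expression vs irAE occurrence in a validation cohort
#'
#' Splits patients into irAE-positive (worst grade >= `grade_cut`) and
#' irAE-negative groups and compares the gene's expression by Mann-Whitney,
#' reporting the group medians.
#'
#' @param cohort data.frame with patient_id, therapy_class, irae_grade and
#'   one column per gene (TPM).
#' @param gene gene column to test.
#' @param grade_cut irAE occurrence is defined as worst grade >= this
#'   (default 1).
#' @return list of class `irae_assoc`: `gene`, `median_irae`,
#'   `median_no_irae`, `U`, `p`, `n_irae`, `n_no_irae`.
#' @export
irae_association <- function(cohort, gene, grade_cut = 1) {
  validate_cohort(cohort, gene)
  pos <- cohort$irae_grade >= grade_cut
  if (!any(pos) || all(pos))
    stop_degenerate("one irAE-status group is empty")
  a <- cohort[[gene]][pos]
  b <- cohort[[gene]][!pos]
  mw <- mann_whitney(a, b)
  structure(list(gene = gene,
                 median_irae = stats::median(a),
                 median_no_irae = stats::median(b),
                 U = mw$U, p = mw$p, exact = mw$exact,
                 n_irae = length(a), n_no_irae = length(b)),
            class = "irae_assoc")
}

#' @export
print.irae_assoc <- function(x, ...) {
  cat(sprintf("%s: median %.3g (irAE, n = %d) vs %.3g (no irAE, n = %d); Mann-Whitney U = %g, p = %.3g\n",
              x$gene, x$median_irae, x$n_irae, x$median_no_irae, x$n_no_irae,
              x$U, x$p))
  invisible(x)
}

#' Therapy-class-adjusted association of expression with irAE occurrence
#'
#' Logistic regression of irAE occurrence (grade >= `grade_cut`) on the
#' gene's expression with the therapy class as a covariate, fitted by
#' iteratively reweighted least squares ([stats::glm()]). Returns the
#' expression coefficient (log-odds per expression unit) and its two-sided
#' Wald p-value. Complete separation is reported as a non-convergence error
#' rather than a silently huge coefficient.
#'
#' @param cohort validation cohort data.frame.
#' @param gene gene column.
#' @param grade_cut irAE binarization threshold.
#' @return list: `coefficient`, `se`, `p`, `therapy_coefficient`, `n`.
#' @export
adjusted_association <- function(cohort, gene, grade_cut = 1) {
  validate_cohort(cohort, gene)
  y <- as.numeric(cohort$irae_grade >= grade_cut)
  if (length(unique(y)) < 2)
    stop_degenerate("irAE outcome is constant; logistic model undefined")
  expr <- cohort[[gene]]
  therapy <- factor(cohort$therapy_class)
  df <- data.frame(y = y, expr = expr)
  one_class <- nlevels(therapy) < 2
  if (!one_class) df$therapy <- therapy
  form <- if (one_class) y ~ expr else y ~ expr + therapy
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    stop_degenerate(paste("logistic fit did not converge (possible complete",
                          "separation between expression/therapy and irAE status)"))
  sm <- summary(fit)$coefficients
  list(coefficient = sm["expr", "Estimate"],
       se = sm["expr", "Std. Error"],
       p = sm["expr", "Pr(>|z|)"],
       therapy_coefficient = if (!one_class)
         sm[grep("^therapy", rownames(sm)), "Estimate"] else NA_real_,
       n = length(y))
}

#' Grade-wise expression comparisons against a reference grade
#'
#' Reports the median expression per worst-irAE grade and a Mann-Whitney
#' test of each grade group against the reference grade group (default: the
#' most severe grade present).
#'
#' @param cohort validation cohort data.frame.
#' @param gene gene column.
#' @param reference_grade grade whose group is the comparator (default 4).
#' @return data.frame: grade, n, median, U, p (reference row carries its
#'   median with NA test fields and is excluded from comparisons).
#' @export
grade_comparisons <- function(cohort, gene, reference_grade = 4) {
  validate_cohort(cohort, gene)
  grades <- sort(unique(cohort$irae_grade))
  if (length(grades) < 2)
    stop_degenerate("all patients share one irAE grade")
  if (!reference_grade %in% grades)
    stop_input("reference grade %d has no patients", reference_grade)
  ref <- cohort[[gene]][cohort$irae_grade == reference_grade]
  rows <- lapply(grades, function(g) {
    v <- cohort[[gene]][cohort$irae_grade == g]
    if (g == reference_grade)
      return(data.frame(grade = g, n = length(v), median = stats::median(v),
                        U = NA_real_, p = NA_real_))
    mw <- mann_whitney(v, ref)
    data.frame(grade = g, n = length(v), median = stats::median(v),
               U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "gene") <- gene
  attr(out, "reference_grade") <- reference_grade
  out
}
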