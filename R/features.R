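# Immunogenomic factor computation and per-cancer-type median aggregation.

#' Tumor mutational burden from a nonsynonymous mutation count
#'
#' TMB is the log-transformed count of nonsynonymous somatic mutations:
#' `log(count + offset, base)` with base 10 and offset 1 by default. The base
#' rescales regression coefficients but leaves correlations unchanged.
#'
#' @param count nonnegative mutation count (vectorized).
#' @param base logarithm base (default 10).
#' @param offset added before the log (default 1 so a count of 0 maps to 0).
#' @return numeric vector of TMB values.
#' @examples
#' compute_tmb(c(0, 99, 999))  # 0, 2, 3
#' @export
compute_tmb <- function(count, base = 10, offset = 1) {
  if (!is.numeric(count) || any(is.na(count)) || any(count < 0))
    stop_input("'count' must be nonnegative")
  log(count + offset, base = base)
}

#' Score a gene-set signature per patient
#'
#' Two conventions: `mean_log` is the arithmetic mean of `log2(value + 1)`
#' over the set genes (used for interferon-gamma-type signatures);
#' `geometric_mean` is `exp(mean(log(value + eps)))` with `eps = 0.01`, the
#' cytolytic-index convention (geometric mean of e.g. GZMA and PRF1).
#' Set genes absent from the matrix are dropped with a warning.
#'
#' @param expr feature-by-patient numeric matrix (nonnegative expression).
#' @param genes character vector of feature ids in the set.
#' @param scoring `"mean_log"` or `"geometric_mean"`.
#' @param eps pseudo-value added inside the geometric mean.
#' @return named numeric vector, one score per patient.
#' @export
signature_score <- function(expr, genes,
                            scoring = c("mean_log", "geometric_mean"),
                            eps = 0.01) {
  scoring <- match.arg(scoring)
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop_input("'expr' must be a matrix with feature rownames")
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0)
    stop_input("no signature gene present in the expression matrix")
  if (length(present) < length(genes))
    warning(sprintf("%d/%d signature genes missing from matrix; dropped",
                    length(genes) - length(present), length(genes)))
  sub <- expr[present, , drop = FALSE]
  if (scoring == "mean_log") {
    colMeans(log2(sub + 1))
  } else {
    exp(colMeans(log(sub + eps)))
  }
}

#' Proportion of PD-1-high patients per cancer type
#'
#' The cutoff is a percentile (default 80th) of the pooled all-patient
#' distribution of the PD-1 (PDCD1) feature, computed with the
#' linear-interpolation quantile; the returned value per cancer type is the
#' fraction of its patients strictly above the cutoff (so an all-equal cohort
#' has proportion 0 everywhere).
#'
#' @param expr feature-by-patient matrix.
#' @param cancer_type character vector of cancer types aligned to the matrix
#'   columns.
#' @param gene_id PD-1 feature id (default "PDCD1").
#' @param percentile pooled cutoff percentile in (0, 100).
#' @return named numeric vector: proportion per cancer type, in [0, 1].
#' @export
pd1_high_proportion <- function(expr, cancer_type, gene_id = "PDCD1",
                                percentile = 80) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop_input("'expr' must be a matrix with feature rownames")
  if (!gene_id %in% rownames(expr))
    stop_input("feature '%s' absent from the expression matrix", gene_id)
  assert_scalar_number(percentile, "percentile", min = 1e-9, max = 100 - 1e-9)
  if (length(cancer_type) != ncol(expr))
    stop_input("'cancer_type' must match the matrix columns")
  v <- expr[gene_id, ]
  cutoff <- stats::quantile(v, percentile / 100, names = FALSE, type = 7)
  ut <- unique(cancer_type)
  prop <- tapply(v > cutoff, cancer_type, mean)[ut]
  stats::setNames(as.numeric(prop), ut)
}

#' Preprocess an expression matrix
#'
#' Applies the `log2(value + 1)` transform and removes features whose
#' per-cancer-type median is zero in more than half of the cancer types
#' (uninformative features for median-based across-type screening). Each
#' omics kind is preprocessed independently.
#'
#' @param expr feature-by-patient matrix of nonnegative values.
#' @param cancer_type cancer type per matrix column; if omitted the
#'   zero-median filter treats all patients as one group.
#' @return transformed, filtered matrix.
#' @export
preprocess_expression <- function(expr, cancer_type = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_input("'expr' must be a numeric matrix")
  if (any(expr < 0)) stop_input("expression values must be nonnegative")
  if (is.null(cancer_type)) cancer_type <- rep("all", ncol(expr))
  if (length(cancer_type) != ncol(expr))
    stop_input("'cancer_type' must match the matrix columns")
  types <- unique(cancer_type)
  zero_med <- vapply(types, function(k) {
    apply(expr[, cancer_type == k, drop = FALSE], 1, stats::median) == 0
  }, logical(nrow(expr)))
  keep <- rowMeans(matrix(zero_med, nrow = nrow(expr))) <= 0.5
  if (!any(keep))
    stop_degenerate("no feature left after the zero-median filter")
  log2(expr[keep, , drop = FALSE] + 1)
}

read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_input("malformed GMT line: %s", l)
    scoring <- if (grepl("geometric", f[2], ignore.case = TRUE))
      "geometric_mean" else "mean_log"
    list(name = f[1], scoring = scoring, genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Assemble the cancer-type by factor median matrix
#'
#' Computes every per-patient factor (TMB, cell-type enrichment scores,
#' signature scores, checkpoint gene expression, preprocessed omics
#' features), takes the per-cancer-type median of each, attaches the
#' PD-1-high proportion (a proportion, not a median), and aligns the ROR
#' outcome vector. Cancer types present in only one of cohort and ROR table
#' are dropped with a warning.
#'
#' @param patients data.frame with columns patient_id, cancer_type,
#'   nonsynonymous_mutation_count, plus one column per cell type (enrichment
#'   scores in [0, 1]); additional numeric columns are carried along as
#'   extra factors.
#' @param omics named list of feature-by-patient matrices (names used as the
#'   screen family, e.g. mrna, mirna, protein); may be empty.
#' @param signatures list of gene sets (each `list(name, genes, scoring)`),
#'   e.g. from [read_gmt()]; scored on the `mrna` matrix.
#' @param ror a `ror_table` from [ror_by_cancer()], or a data.frame with
#'   columns cancer_type and ror.
#' @param pd1_gene PD-1 feature id in the mrna matrix (NULL to skip the
#'   PD-1-high factor).
#' @param pd1_percentile pooled percentile for the PD-1-high cutoff.
#' @param checkpoint_genes genes whose (log2) expression is medianized as a
#'   checkpoint factor, if present in the mrna matrix.
#' @param tmb_base,tmb_offset TMB transform, see [compute_tmb()].
#' @return object of class `factor_matrix`: list with `values` (data.frame,
#'   rows = cancer types, columns = factors), `outcome` (named ROR vector)
#'   and `family` (screen family per factor: "panel" or the omics kind).
#' @export
median_factor_matrix <- function(patients, omics = list(), signatures = list(),
                                 ror, pd1_gene = "PDCD1", pd1_percentile = 80,
                                 checkpoint_genes = c("PDCD1", "CD274"),
                                 tmb_base = 10, tmb_offset = 1) {
  req <- c("patient_id", "cancer_type", "nonsynonymous_mutation_count")
  if (!is.data.frame(patients) || !all(req %in% names(patients)))
    stop_input("patient table needs columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(patients$patient_id))
    stop_input("duplicate patient_id in patient table")
  ror_df <- as.data.frame(ror)
  if (!all(c("cancer_type", "ror") %in% names(ror_df)))
    stop_input("'ror' needs columns cancer_type and ror")

  # order follows the ROR table so the result is invariant to patient order
  shared <- intersect(ror_df$cancer_type, unique(patients$cancer_type))
  dropped <- setdiff(union(unique(patients$cancer_type), ror_df$cancer_type),
                     shared)
  if (length(dropped))
    warning(sprintf("dropping %d cancer type(s) without both cohort and ROR: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (length(shared) < 3)
    stop_degenerate("fewer than 3 cancer types shared between cohort and ROR")
  patients <- patients[patients$cancer_type %in% shared, , drop = FALSE]
  ct <- patients$cancer_type

  per_patient <- list(
    log_TMB = compute_tmb(patients$nonsynonymous_mutation_count,
                          base = tmb_base, offset = tmb_offset))
  family <- c(log_TMB = "panel")

  cell_cols <- setdiff(names(patients), req)
  cell_cols <- cell_cols[vapply(patients[cell_cols], is.numeric, logical(1))]
  for (cc in cell_cols) {
    per_patient[[cc]] <- patients[[cc]]
    family[cc] <- "panel"
  }

  mrna <- omics[["mrna"]]
  if (!is.null(mrna)) {
    mrna <- mrna[, match(patients$patient_id, colnames(mrna)), drop = FALSE]
    if (anyNA(colnames(mrna)))
      stop_input("mrna matrix is missing some cohort patients")
    for (s in signatures) {
      per_patient[[s$name]] <- signature_score(mrna, s$genes, s$scoring)
      family[s$name] <- "panel"
    }
    for (g in intersect(checkpoint_genes, rownames(mrna))) {
      nm <- paste0(g, "_expr")
      per_patient[[nm]] <- log2(mrna[g, ] + 1)
      family[nm] <- "panel"
    }
  }

  med_by_type <- function(v)
    as.numeric(tapply(v, ct, stats::median, na.rm = TRUE)[shared])
  values <- as.data.frame(lapply(per_patient, med_by_type),
                          check.names = FALSE)
  rownames(values) <- shared

  if (!is.null(mrna) && !is.null(pd1_gene) && pd1_gene %in% rownames(mrna)) {
    values$PD1_high_prop <-
      as.numeric(pd1_high_proportion(mrna, ct, pd1_gene,
                                     pd1_percentile)[shared])
    family["PD1_high_prop"] <- "panel"
  }

  for (kind in names(omics)) {
    mat <- omics[[kind]][, match(patients$patient_id,
                                 colnames(omics[[kind]])), drop = FALSE]
    proc <- preprocess_expression(mat, ct)
    for (f in rownames(proc)) {
      values[[f]] <- as.numeric(med_by_type(proc[f, ]))
      family[f] <- kind
    }
  }

  low_n <- vapply(values, function(v) sum(!is.na(v)) < 3, logical(1))
  if (any(low_n)) {
    warning(sprintf("dropping %d factor(s) with < 3 non-missing values",
                    sum(low_n)))
    values <- values[, !low_n, drop = FALSE]
    family <- family[colnames(values)]
  }

  outcome <- ror_df$ror[match(shared, ror_df$cancer_type)]
  names(outcome) <- shared
  if (anyNA(outcome)) stop_input("missing ROR outcome for a shared type")

  structure(list(values = values, outcome = outcome,
                 family = family[colnames(values)]),
            class = "factor_matrix")
}

#' @export
print.factor_matrix <- function(x, ...) {
  cat(sprintf("Factor matrix: %d cancer types x %d factors (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$family)),
                            table(x$family)), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.factor_matrix <- function(x, ...) {
  cbind(data.frame(cancer_type = rownames(x$values), ror = x$outcome,
                   row.names = NULL), x$values, row.names = NULL)
}
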