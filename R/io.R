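# Plain-text I/O: TSV tables with semicolon-delimited multi-valued fields,
# GMT gene sets (read_gmt in features.R), and term lists (read_irae_terms in
# pharmacovigilance.R). All files are UTF-8 with a header row.

read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a spontaneous-report table
#'
#' Tab-separated, one report per row, header required; the multi-valued
#' `drugs` and `reactions` fields are semicolon-delimited.
#'
#' @param path file path.
#' @return report data.frame.
#' @export
read_reports <- function(path) validate_reports(read_tsv(path))

#' @rdname read_reports
#' @param reports report data.frame.
#' @export
write_reports <- function(reports, path) write_tsv(validate_reports(reports), path)

#' Read / write an expression matrix (features x patients)
#'
#' TSV with feature ids in the first column and one column per patient.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop_input("expression table needs >= 2 columns")
  if (anyDuplicated(df[[1]])) stop_input("duplicate feature ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression
#' @param expr feature-by-patient matrix.
#' @export
write_expression <- function(expr, path) {
  write_tsv(cbind(data.frame(feature_id = rownames(expr)),
                  as.data.frame(expr, check.names = FALSE)), path)
}

#' Read / write a factor matrix
#'
#' TSV with columns cancer_type, ror, then one column per factor. The file
#' does not carry screen families: on read, every factor defaults to the
#' "panel" family unless a `families` vector is supplied.
#'
#' @param path file path.
#' @param families optional named character vector factor -> family.
#' @return a `factor_matrix`.
#' @export
read_factor_matrix <- function(path, families = NULL) {
  df <- read_tsv(path)
  if (!all(c("cancer_type", "ror") %in% names(df)))
    stop_input("factor matrix file needs cancer_type and ror columns")
  vals <- df[, setdiff(names(df), c("cancer_type", "ror")), drop = FALSE]
  rownames(vals) <- df$cancer_type
  fam <- stats::setNames(rep("panel", ncol(vals)), colnames(vals))
  if (!is.null(families)) fam[names(families)] <- families
  outcome <- stats::setNames(df$ror, df$cancer_type)
  structure(list(values = vals, outcome = outcome, family = fam),
            class = "factor_matrix")
}

#' @rdname read_factor_matrix
#' @param fm a `factor_matrix`.
#' @export
write_factor_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "factor_matrix"))
  write_tsv(as.data.frame(fm), path)
}

#' Read a validation cohort
#'
#' Patient metadata TSV (patient_id, therapy_class, irae_grade) plus an
#' expression TSV in TPM (genes x patients), merged into one wide data.frame.
#'
#' @param meta_path metadata file.
#' @param expr_path expression matrix file.
#' @return cohort data.frame.
#' @export
read_cohort <- function(meta_path, expr_path) {
  meta <- read_tsv(meta_path)
  expr <- read_expression(expr_path)
  validate_cohort(meta)
  miss <- setdiff(meta$patient_id, colnames(expr))
  if (length(miss))
    stop_input("expression matrix is missing patients: %s",
               paste(utils::head(miss, 5), collapse = ", "))
  cbind(meta, as.data.frame(t(expr[, meta$patient_id, drop = FALSE]),
                            check.names = FALSE), row.names = NULL)
}
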