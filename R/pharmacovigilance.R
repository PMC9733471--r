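# Pharmacovigilance stage: monotherapy filtering, irAE classification by
# preferred-term matching, and per-cancer-type reporting odds ratios.

#' irAE preferred-term list
#'
#' Wraps a set of MedDRA-style preferred terms used to classify a report as
#' containing at least one immune-related adverse event. Matching is exact
#' after case-folding and whitespace trimming (controlled vocabulary; no
#' fuzzy matching). The list shipped with the package
#' (`system.file("extdata", "irae_terms_default.txt", package = "iraescreen")`)
#' is a documented synthetic placeholder: any real analysis must supply its
#' own versioned term list.
#'
#' @param terms character vector of preferred terms.
#' @return object of class `irae_terms` (normalized, deduplicated).
#' @export
irae_terms <- function(terms) {
  if (!is.character(terms)) stop_input("'terms' must be a character vector")
  norm <- unique(normalize_term(terms))
  norm <- norm[nzchar(norm)]
  if (length(norm) == 0) stop_input("term list is empty after normalization")
  structure(list(terms = norm), class = "irae_terms")
}

#' @export
print.irae_terms <- function(x, ...) {
  cat(sprintf("irAE preferred-term list: %d terms\n", length(x$terms)))
  utils::head(x$terms, 5) |> paste(collapse = ", ") |> cat("...\n")
  invisible(x)
}

#' Read an irAE term list from a plain-text file
#'
#' One term per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return an [irae_terms()] object.
#' @export
read_irae_terms <- function(path) {
  if (!file.exists(path)) stop_input("term file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  irae_terms(lines[nzchar(lines)])
}

validate_reports <- function(reports) {
  req <- c("report_id", "drugs", "indication", "reactions")
  if (!is.data.frame(reports) || !all(req %in% names(reports)))
    stop_input("report table needs columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(reports$report_id))
    stop_input("duplicate report_id in report table")
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  if (any(blank(reports$indication)))
    stop_input("empty indication in report table")
  if (any(blank(reports$reactions)))
    stop_input("empty reaction list in report table")
  invisible(reports)
}

#' Restrict a report table to a monotherapy stratum
#'
#' Retains exactly the reports whose suspected drugs intersect `target_drugs`
#' and do not intersect `excluded_cotreatments` (e.g. anti-PD-1 agents, with
#' ipilimumab combinations excluded). Drug names are matched after
#' case-folding and trimming; row order is preserved.
#'
#' @param reports report data.frame (columns report_id, drugs, indication,
#'   reactions; multi-valued fields semicolon-delimited).
#' @param target_drugs character vector of suspected drugs to keep.
#' @param excluded_cotreatments drugs whose presence disqualifies a report.
#' @return filtered report data.frame (possibly zero rows).
#' @export
filter_monotherapy <- function(reports,
                               target_drugs = c("nivolumab", "pembrolizumab"),
                               excluded_cotreatments = "ipilimumab") {
  validate_reports(reports)
  if (length(target_drugs) == 0) stop_input("'target_drugs' must be nonempty")
  tgt <- normalize_term(target_drugs)
  excl <- normalize_term(excluded_cotreatments)
  sets <- strsplit(reports$drugs, ";", fixed = TRUE)
  flat <- normalize_term(unlist(sets))
  row <- rep(seq_along(sets), lengths(sets))
  has_tgt <- has_excl <- logical(nrow(reports))
  has_tgt[unique(row[flat %in% tgt])] <- TRUE
  has_excl[unique(row[flat %in% excl])] <- TRUE
  reports[has_tgt & !has_excl, , drop = FALSE]
}

#' Classify a report's reactions as containing an irAE
#'
#' TRUE iff at least one reaction term matches the irAE preferred-term list
#' after normalization.
#'
#' @param report_reactions character vector of reaction preferred terms for
#'   one report (must be nonempty).
#' @param terms an [irae_terms()] object.
#' @return logical scalar.
#' @export
classify_irae <- function(report_reactions, terms) {
  stopifnot(inherits(terms, "irae_terms"))
  rx <- normalize_term(report_reactions)
  rx <- rx[nzchar(rx)]
  if (length(rx) == 0) stop_input("report has an empty reaction list")
  any(rx %in% terms$terms)
}

# Vectorized at-least-one-irAE classification over semicolon-delimited
# reaction strings; same normalization rule as classify_irae().
classify_irae_vec <- function(reactions, terms) {
  stopifnot(inherits(terms, "irae_terms"))
  sets <- strsplit(as.character(reactions), ";", fixed = TRUE)
  flat <- normalize_term(unlist(sets))
  keep <- nzchar(flat)
  row <- rep(seq_along(sets), lengths(sets))[keep]
  if (!all(seq_along(sets) %in% row))
    stop_input("report has an empty reaction list")
  out <- logical(length(sets))
  out[unique(row[flat[keep] %in% terms$terms])] <- TRUE
  out
}

#' Reporting odds ratio from a 2x2 contingency table
#'
#' The table is (index stratum vs comparator) x (irAE vs non-irAE):
#' `a` irAE reports in the index stratum, `b` non-irAE in the index stratum,
#' `c` irAE in the comparator, `d` non-irAE in the comparator. ROR =
#' (a*d)/(b*c) with a 95\% Wald interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With
#' `correction = "haldane"` (default), 0.5 is added to all four cells only
#' when any cell is zero.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @param correction `"haldane"` or `"none"`.
#' @param conf_level confidence level of the Wald interval.
#' @return list with `ror`, `ci_low`, `ci_high`, the (corrected) `counts`,
#'   and `corrected` flag.
#' @examples
#' ror_from_counts(20, 80, 10, 90)$ror  # 2.25
#' @export
ror_from_counts <- function(a, b, c, d, correction = c("haldane", "none"),
                            conf_level = 0.95) {
  correction <- match.arg(correction)
  for (v in list(a, b, c, d)) assert_count(v, "cell count", min = 0L)
  counts <- c(a = a, b = b, c = c, d = d)
  corrected <- FALSE
  if (any(counts == 0)) {
    if (correction == "haldane") {
      counts <- counts + 0.5
      corrected <- TRUE
    } else if (b * c == 0) {
      stop_degenerate("zero cell makes the ROR undefined (correction disabled)")
    }
  }
  ror <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ror = unname(ror),
       ci_low = unname(exp(log(ror) - z * se)),
       ci_high = unname(exp(log(ror) + z * se)),
       counts = counts, corrected = corrected)
}

#' Per-cancer-type reporting odds ratios
#'
#' For each cancer type in an (already monotherapy-filtered) report table,
#' builds the 2x2 contingency table against the pooled other cancer types in
#' the same stratum — or against an explicit external `comparator` table —
#' and computes the ROR with its Wald interval.
#'
#' @param reports filtered report data.frame (>= 2 distinct cancer types
#'   unless `comparator` is given).
#' @param terms an [irae_terms()] object.
#' @param correction zero-cell handling, see [ror_from_counts()].
#' @param comparator optional report data.frame used as the comparator
#'   stratum instead of the other cancer types of `reports`.
#' @param conf_level confidence level for the Wald interval.
#' @return data.frame of class `ror_table`: cancer_type, n_reports, n_irae,
#'   a, b, c, d, ror, ci_low, ci_high; attributes `n_total` and
#'   `n_irae_total` carry the overall case counts.
#' @export
ror_by_cancer <- function(reports, terms, correction = c("haldane", "none"),
                          comparator = NULL, conf_level = 0.95) {
  validate_reports(reports)
  correction <- match.arg(correction)
  is_irae <- classify_irae_vec(reports$reactions, terms)
  types <- unique(reports$indication)
  if (is.null(comparator) && length(types) < 2)
    stop_degenerate("need >= 2 cancer types for a pooled comparator")

  if (!is.null(comparator)) {
    validate_reports(comparator)
    comp_irae <- classify_irae_vec(comparator$reactions, terms)
  }

  rows <- lapply(types, function(k) {
    idx <- reports$indication == k
    a <- sum(is_irae & idx)
    b <- sum(!is_irae & idx)
    if (is.null(comparator)) {
      cc <- sum(is_irae & !idx)
      dd <- sum(!is_irae & !idx)
    } else {
      keep <- comparator$indication != k
      cc <- sum(comp_irae[keep])
      dd <- sum(!comp_irae[keep])
    }
    r <- ror_from_counts(a, b, cc, dd, correction = correction,
                         conf_level = conf_level)
    data.frame(cancer_type = k, n_reports = a + b, n_irae = a,
               a = a, b = b, c = cc, d = dd,
               ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- nrow(reports)
  attr(out, "n_irae_total") <- sum(is_irae)
  class(out) <- c("ror_table", "data.frame")
  out
}

#' @export
print.ror_table <- function(x, digits = 3, ...) {
  cat(sprintf("Reporting odds ratios for %d cancer types (%d reports, %d with >=1 irAE, %.2f%%)\n",
              nrow(x), attr(x, "n_total"), attr(x, "n_irae_total"),
              percent_irae(attr(x, "n_irae_total"), attr(x, "n_total"))))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ror_table <- function(object, ...) {
  n_total <- attr(object, "n_total")
  n_irae <- attr(object, "n_irae_total")
  res <- list(n_types = nrow(object),
              n_total = n_total,
              n_irae = n_irae,
              percent_irae = percent_irae(n_irae, n_total),
              ror_range = range(object$ror),
              lowest = object$cancer_type[which.min(object$ror)],
              highest = object$cancer_type[which.max(object$ror)])
  class(res) <- "summary.ror_table"
  res
}

#' @export
print.summary.ror_table <- function(x, ...) {
  cat(sprintf("%d eligible cases across %d cancer types; %d (%.2f%%) with >= 1 irAE\n",
              x$n_total, x$n_types, x$n_irae, x$percent_irae))
  cat(sprintf("ROR range: %.2f (%s) to %.2f (%s)\n",
              x$ror_range[1], x$lowest, x$ror_range[2], x$highest))
  invisible(x)
}
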