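#' @keywords internal
"_PACKAGE"

# Condition helpers: classed errors so the CLI can map failures to exit codes
# (input errors -> 2, degenerate-statistics errors -> 3).

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("irae_input_error", "error", "condition")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("irae_config_error", "irae_input_error",
                                "error", "condition")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("irae_degenerate_error", "error", "condition")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_config("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x)))
    stop_config("'%s' must be integer-valued and >= %d", name, min)
  invisible(x)
}

#' Normalize a controlled-vocabulary term
#'
#' Case-folds and trims whitespace; collapses internal runs of whitespace.
#' Used for MedDRA preferred terms and drug names so that matching is exact
#' after normalization (no fuzzy matching).
#'
#' @param x character vector of terms.
#' @return normalized character vector.
#' @keywords internal
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Deterministic per-table seed stream: a single global seed feeds every
# simulated table through a distinct stream id, so adding one omics layer
# never perturbs the report table. Kept below 2^31 (R integers are 32-bit).
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + stream * 104729) %%
               2147483647)
}

split_multi <- function(x, sep = ";") {
  lapply(strsplit(as.character(x), sep, fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

join_multi <- function(x, sep = ";") {
  vapply(x, paste, character(1), collapse = sep)
}

#' Unexplained variance of a correlation-scored prediction
#'
#' Bookkeeping used throughout model reporting: a model whose held-out
#' predictions correlate with the observed outcome at Pearson R leaves
#' 1 - R^2 of the outcome variance unexplained.
#'
#' @param r Pearson correlation coefficient (length-1 or vector), |r| <= 1.
#' @return 1 - r^2, same shape as `r`.
#' @examples
#' unexplained_variance(0.63)  # TMB-only model
#' unexplained_variance(0.81)  # DC + TMB + naive CD4 T-cell model
#' @export
unexplained_variance <- function(r) {
  if (!is.numeric(r) || any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_input("'r' must be numeric with |r| <= 1")
  1 - r^2
}

#' Percentage of cases with at least one irAE
#'
#' @param n_irae number of cases with >= 1 immune-related adverse event.
#' @param n_total total number of eligible cases.
#' @return percentage on the 0-100 scale.
#' @examples
#' percent_irae(2997, 10412)
#' @export
percent_irae <- function(n_irae, n_total) {
  assert_count(n_irae, "n_irae", min = 0L)
  assert_count(n_total, "n_total", min = 1L)
  if (n_irae > n_total) stop_input("n_irae exceeds n_total")
  100 * n_irae / n_total
}
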