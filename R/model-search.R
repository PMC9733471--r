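# Exhaustive enumeration of uni/bi/trivariate ROR models, scored by LOOCV,
# screened for collinearity (VIF) and nested improvement (LR tests), with BH
# control of the LOOCV p-values within each model-size family.

#' Enumerate and rank candidate linear models of the ROR
#'
#' Fits every unordered subset of `candidates` of each requested size,
#' scores each by leave-one-out cross-validated Pearson R, computes VIFs
#' (size >= 2), and tests every model against each of its nested parents by
#' likelihood ratio (size-1 models are tested against the intercept-only
#' model). BH FDR is applied to the LOOCV p-values within each size family.
#' A model is *admissible* iff all parent LR tests have p below `lr_alpha`
#' and no VIF exceeds `vif_limit`. Models are ranked by LOOCV R descending;
#' ties break toward fewer predictors, then lexicographic predictor names.
#'
#' @param fm a `factor_matrix` (or data.frame with a `ror` column).
#' @param candidates factor names to combine; defaults to the panel-family
#'   factors of `fm`.
#' @param sizes model sizes to enumerate (subset of 1:3 typically).
#' @param vif_limit collinearity threshold (default 4).
#' @param lr_alpha significance level for parent LR tests (default 0.05).
#' @return object of class `ror_search`: `table` (one row per model) and
#'   `fits` (named list of `ror_model` objects, keyed by
#'   `paste(predictors, collapse = " + ")`).
#' @export
search_ror_models <- function(fm, candidates = NULL, sizes = 1:3,
                              vif_limit = 4, lr_alpha = 0.05) {
  df <- model_frame_data(fm)
  if (!"ror" %in% colnames(df)) stop_input("'fm' must carry a 'ror' outcome")
  if (is.null(candidates)) {
    if (!inherits(fm, "factor_matrix"))
      stop_input("'candidates' required when 'fm' is a plain data.frame")
    candidates <- names(fm$family)[fm$family == "panel"]
  }
  miss <- setdiff(candidates, colnames(df))
  if (length(miss))
    stop_input("candidate(s) not in factor matrix: %s",
               paste(miss, collapse = ", "))
  n <- nrow(df)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > length(candidates)))
    stop_input("'sizes' must lie in 1..length(candidates)")
  if (max(sizes) >= n - 2)
    stop_degenerate("largest model size %d needs more cancer types (n = %d)",
                    max(sizes), n)

  null_fit <- ror_model(ror ~ 1, df, loocv = FALSE)
  key <- function(v) paste(sort(v), collapse = " + ")

  fits <- list()
  rows <- list()
  for (k in sizes) {
    subsets <- utils::combn(sort(candidates), k, simplify = FALSE)
    for (s in subsets) {
      f <- stats::reformulate(sprintf("`%s`", s), response = "ror")
      fit <- tryCatch(ror_model(f, df), irae_degenerate_error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1]] <-
          data.frame(model = key(s), size = k, loocv_r = NA_real_,
                     loocv_p = NA_real_, fdr = NA_real_,
                     unexplained_variance = NA_real_, vif_max = NA_real_,
                     lr_max_p = NA_real_, admissible = FALSE,
                     note = conditionMessage(fit))
        next
      }
      fits[[key(s)]] <- fit
      parents <- if (k == 1) list(character(0)) else
        utils::combn(s, k - 1, simplify = FALSE)
      lr_p <- vapply(parents, function(p) {
        pf <- if (length(p) == 0) null_fit else fits[[key(p)]]
        if (is.null(pf)) {  # parent size not enumerated: fit on demand
          pf <- ror_model(stats::reformulate(sprintf("`%s`", p),
                                             response = "ror"),
                          df, loocv = FALSE)
        }
        lr_test(fit, pf)$p.value
      }, numeric(1))
      vmax <- if (is.null(fit$vif)) NA_real_ else max(fit$vif)
      rows[[length(rows) + 1]] <-
        data.frame(model = key(s), size = k, loocv_r = fit$loocv_r,
                   loocv_p = fit$loocv_p, fdr = NA_real_,
                   unexplained_variance = fit$unexplained_variance,
                   vif_max = vmax,
                   lr_max_p = max(lr_p),
                   admissible = all(lr_p < lr_alpha) &&
                     (is.na(vmax) || vmax <= vif_limit),
                   note = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  for (k in unique(tab$size)) {
    idx <- which(tab$size == k & !is.na(tab$loocv_p))
    tab$fdr[idx] <- bh_adjust(tab$loocv_p[idx])
  }
  ord <- order(-tab$loocv_r, tab$size, tab$model, na.last = TRUE)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  structure(list(table = tab, fits = fits, n = n,
                 candidates = sort(candidates),
                 vif_limit = vif_limit, lr_alpha = lr_alpha,
                 call = match.call()),
            class = "ror_search")
}

#' Best-ranked model from a search
#'
#' @param search a `ror_search` object.
#' @param size restrict to a model size (NULL = any).
#' @param admissible_only require all parent LR tests significant and no
#'   VIF above the limit.
#' @return the top `ror_model`.
#' @export
best_model <- function(search, size = NULL, admissible_only = FALSE) {
  stopifnot(inherits(search, "ror_search"))
  tab <- search$table
  if (!is.null(size)) tab <- tab[tab$size %in% size, , drop = FALSE]
  if (admissible_only) tab <- tab[tab$admissible %in% TRUE, , drop = FALSE]
  tab <- tab[!is.na(tab$loocv_r), , drop = FALSE]
  if (nrow(tab) == 0) stop_degenerate("no model matches the constraints")
  search$fits[[tab$model[1]]]
}

#' @export
print.ror_search <- function(x, max_rows = 10, digits = 3, ...) {
  counts <- table(x$table$size)
  cat(sprintf("Model search over %d candidates: %s\n",
              length(x$candidates),
              paste(sprintf("%s models of size %s", counts, names(counts)),
                    collapse = ", ")))
  cat(sprintf("Admissibility: all parent LR p < %.3g and VIF <= %.3g\n",
              x$lr_alpha, x$vif_limit))
  print.data.frame(utils::head(x$table, max_rows), digits = digits,
                   row.names = FALSE)
  if (nrow(x$table) > max_rows)
    cat(sprintf("... and %d more\n", nrow(x$table) - max_rows))
  invisible(x)
}

#' @export
summary.ror_search <- function(object, ...) {
  tab <- object$table
  best_by_size <- do.call(rbind, lapply(split(tab, tab$size), function(g)
    g[which.max(g$loocv_r), , drop = FALSE]))
  structure(list(n_models = nrow(tab),
                 n_admissible = sum(tab$admissible, na.rm = TRUE),
                 best_by_size = best_by_size),
            class = "summary.ror_search")
}

#' @export
print.summary.ror_search <- function(x, ...) {
  cat(sprintf("%d models enumerated, %d admissible\n",
              x$n_models, x$n_admissible))
  cat("Best model per size:\n")
  print.data.frame(x$best_by_size, digits = 3, row.names = FALSE)
  invisible(x)
}
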