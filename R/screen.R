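# Across-cancer-type Pearson screening with Benjamini-Hochberg FDR control.

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson r and the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom;
#' exact linearity (|r| = 1) yields p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with a missing
#'   value in either vector are dropped first.
#' @return list with `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_r_p <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_input("'x' and 'y' must be numeric vectors of equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_degenerate("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1 - 1e-15) 0 else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: the i-th smallest p becomes
#' `min_{j >= i} p_(j) * m / j`, clipped at 1 and mapped back to input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NAs propagate).
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop_input("'pvalues' must be numeric")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen factors against the ROR across cancer types
#'
#' Correlates every factor column of a [median_factor_matrix()] result with
#' the ROR outcome (Pearson, pairwise-complete) and applies BH FDR control
#' within each screen family: the curated immunogenomic panel is one family
#' and each molecular kind (mrna, mirna, protein, ...) its own family.
#' Factors that fail preconditions (constant across types, < 3 complete
#' pairs) are reported with a reason and excluded from the FDR family size.
#'
#' @param fm a `factor_matrix`.
#' @param families optional named character vector overriding the stored
#'   factor-to-family assignment.
#' @param alpha significance threshold recorded for convenience.
#' @return data.frame of class `irae_screen`: factor, family, n, r, p, fdr,
#'   significant, reason; sorted by |r| descending within family.
#' @export
screen_factors <- function(fm, families = NULL, alpha = 0.05) {
  if (!inherits(fm, "factor_matrix")) stop_input("'fm' must be a factor_matrix")
  if (ncol(fm$values) == 0) stop_input("factor matrix has no factor columns")
  fam <- fm$family
  if (!is.null(families)) fam[names(families)] <- families
  y <- fm$outcome

  X <- as.matrix(fm$values)
  nfac <- ncol(X)
  n_used <- integer(nfac); r <- p <- rep(NA_real_, nfac)
  reason <- rep(NA_character_, nfac)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  y_ok <- nrow(X) >= 3 && !anyNA(y) && stats::sd(y) > 0
  fast <- y_ok & colSums(is.na(X)) == 0 & !is.na(sds) & sds > 0
  if (any(fast)) {
    # whole-matrix Pearson with the same t-transform as pearson_r_p
    nn <- nrow(X)
    rf <- suppressWarnings(stats::cor(X[, fast, drop = FALSE], y))[, 1]
    tt <- rf * sqrt(nn - 2) / sqrt(pmax(1 - rf^2, 0))
    pf <- ifelse(abs(rf) >= 1 - 1e-15, 0,
                 2 * stats::pt(abs(tt), df = nn - 2, lower.tail = FALSE))
    r[fast] <- rf; p[fast] <- pf; n_used[fast] <- nn
  }
  for (j in which(!fast)) {
    x <- X[, j]
    ok <- stats::complete.cases(x, y)
    n_used[j] <- sum(ok)
    if (sum(ok) < 3) { reason[j] <- "fewer than 3 complete pairs"; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      reason[j] <- "constant values"; next
    }
    pr <- pearson_r_p(x, y)
    r[j] <- pr$r; p[j] <- pr$p; n_used[j] <- pr$n
  }
  out <- data.frame(factor = colnames(X), family = unname(fam[colnames(X)]),
                    n = n_used, r = r, p = p, reason = reason,
                    stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  for (fml in unique(out$family)) {
    idx <- which(out$family == fml & !is.na(out$p))
    out$fdr[idx] <- bh_adjust(out$p[idx])
  }
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  out <- out[order(out$family, -abs(out$r)), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("irae_screen", "data.frame")
  out
}

#' @export
print.irae_screen <- function(x, digits = 3, max_rows = 20, ...) {
  cat(sprintf("Correlation screen: %d factors, %d significant at FDR < %.3g\n",
              nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "alpha")))
  print.data.frame(utils::head(x[order(-abs(x$r)), ], max_rows),
                   digits = digits, row.names = FALSE)
  if (nrow(x) > max_rows) cat(sprintf("... and %d more\n", nrow(x) - max_rows))
  invisible(x)
}
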