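# Linear models of the per-cancer-type ROR: full-data OLS coefficients,
# leave-one-out cross-validated Pearson performance, variance inflation
# factors, and nested likelihood-ratio tests.

SIGMA2_FLOOR <- 1e-12

ml_loglik <- function(rss, n) {
  s2 <- max(rss / n, SIGMA2_FLOOR)
  -(n / 2) * (log(2 * pi * s2) + 1)
}

# Design matrix (with intercept) from predictor names and a data.frame.
build_design <- function(data, predictors) {
  miss <- setdiff(predictors, colnames(data))
  if (length(miss))
    stop_input("predictor(s) not found: %s", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

fit_ols_core <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_degenerate("singular design: predictors are linearly dependent")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  list(coefficients = fit$coefficients, residuals = fit$residuals,
       fitted = fit$fitted.values, rss = rss, n = n,
       loglik = ml_loglik(rss, n),
       degenerate = rss / n < SIGMA2_FLOOR)
}

loocv_predictions <- function(X, y) {
  n <- length(y)
  if (n < 4) stop_degenerate("LOOCV needs n >= 4")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi))
      stop_degenerate("LOOCV fold %d is singular", i)
    cf <- stats::lm.fit(Xi, y[-i])$coefficients
    preds[i] <- drop(X[i, ] %*% cf)
  }
  preds
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` comes from regressing predictor j
#' on the remaining predictors (with intercept). A VIF above the conventional
#' threshold of 4 flags multicollinearity. Perfectly collinear predictors are
#' reported as `Inf` rather than raising an error.
#'
#' @param X numeric matrix or data.frame of predictor columns (>= 2).
#' @return named numeric vector of VIFs with attribute `flagged` (any
#'   VIF > 4).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop_input("VIF needs >= 2 predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    if (stats::sd(yj) == 0) return(Inf)
    res <- stats::lm.fit(Zj, yj)$residuals
    r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "flagged") <- any(out > 4)
  out
}

#' Fit a cross-validated linear model of the reporting odds ratio
#'
#' Fits an ordinary-least-squares linear model of the per-cancer-type ROR on
#' immunogenomic factor medians and scores its predictive performance by
#' leave-one-out cross-validation: each cancer type is held out in turn,
#' the model refit on the remaining types, and the pooled held-out
#' predictions are correlated with the observed ROR (Pearson R, two-sided p).
#' Reported coefficients come from the full-data fit; performance comes from
#' the cross-validation. The Gaussian maximum-likelihood log-likelihood
#' (`sigma^2 = RSS/n`) is stored for nested likelihood-ratio tests, and VIFs
#' are computed for models with >= 2 predictors.
#'
#' @param formula model formula, e.g. `ror ~ DC + log_TMB + naiveCD4T`. The
#'   response defaults to the outcome vector when `data` is a
#'   `factor_matrix`.
#' @param data a `factor_matrix` from [median_factor_matrix()] or a
#'   data.frame containing the response and predictors.
#' @param loocv logical; compute leave-one-out performance (needs n >= 4).
#' @return object of class `ror_model` with components `coefficients`
#'   (including the intercept), `predictors`, `loocv_r`, `loocv_p`,
#'   `loocv_pred`, `unexplained_variance`, `vif`, `loglik`, `rss`, `n`,
#'   `fitted`, `residuals`, `y`, `degenerate`.
#' @examples
#' fm <- data.frame(ror = c(1, 2, 3, 4, 5.5, 6),
#'                  x = c(0.9, 2.1, 3, 3.9, 5.6, 6.2))
#' m <- ror_model(ror ~ x, fm)
#' coef(m); m$loocv_r
#' @export
ror_model <- function(formula, data, loocv = TRUE) {
  df <- model_frame_data(data)
  mf <- stats::model.frame(formula, df)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop_input("response must be numeric")
  predictors <- attr(stats::terms(mf), "term.labels")
  X <- build_design(df[rownames(mf), , drop = FALSE], predictors)
  n <- length(y)
  p <- length(predictors)
  if (n <= p + 1)
    stop_degenerate("need n > p + 1 (n = %d, p = %d)", n, p)

  fit <- fit_ols_core(X, y)
  dfree <- n - p - 1
  sigma2_unbiased <- if (dfree > 0) fit$rss / dfree else NA_real_
  se_coef <- if (!is.na(sigma2_unbiased))
    sqrt(diag(sigma2_unbiased * solve(crossprod(X)))) else
      rep(NA_real_, p + 1)
  res <- list(call = match.call(),
              formula = formula,
              predictors = predictors,
              coefficients = fit$coefficients,
              se_coef = se_coef,
              fitted = fit$fitted,
              residuals = fit$residuals,
              y = y,
              rss = fit$rss,
              loglik = fit$loglik,
              n = n,
              degenerate = fit$degenerate,
              vif = if (p >= 2) vif(X[, -1, drop = FALSE]) else NULL,
              units = rownames(df))

  if (loocv) {
    preds <- loocv_predictions(X, y)
    if (stats::sd(preds) == 0) {
      res$loocv_r <- NA_real_
      res$loocv_p <- NA_real_
    } else {
      pr <- pearson_r_p(preds, y)
      res$loocv_r <- pr$r
      res$loocv_p <- pr$p
    }
    res$loocv_pred <- preds
    res$unexplained_variance <-
      if (is.na(res$loocv_r)) NA_real_ else unexplained_variance(res$loocv_r)
  }
  class(res) <- "ror_model"
  res
}

model_frame_data <- function(data) {
  if (inherits(data, "factor_matrix")) {
    df <- cbind(ror = unname(data$outcome), data$values)
    rownames(df) <- rownames(data$values)
    df
  } else if (is.data.frame(data)) {
    data
  } else {
    stop_input("'data' must be a factor_matrix or data.frame")
  }
}

#' Nested likelihood-ratio test between two ROR models
#'
#' `Lambda = 2 * (loglik_full - loglik_reduced)` referred to a chi-square
#' distribution with df = difference in predictor counts. The reduced model's
#' predictors must be a strict subset of the full model's, fitted to the same
#' response.
#'
#' @param full,reduced `ror_model` fits.
#' @return list of class `lr_test`: `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "ror_model"), inherits(reduced, "ror_model"))
  if (!all(reduced$predictors %in% full$predictors) ||
      length(reduced$predictors) >= length(full$predictors))
    stop_input("models are not strictly nested")
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y)))
    stop_input("models were fitted to different responses")
  lambda <- 2 * (full$loglik - reduced$loglik)
  lambda <- max(lambda, 0)  # guards tiny negative rounding
  df <- length(full$predictors) - length(reduced$predictors)
  structure(list(statistic = lambda, df = df,
                 p.value = stats::pchisq(lambda, df, lower.tail = FALSE),
                 full = paste(full$predictors, collapse = " + "),
                 reduced = if (length(reduced$predictors))
                   paste(reduced$predictors, collapse = " + ") else "1"),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test: [%s] vs [%s]\n  Lambda = %.4g, df = %d, p = %.3g\n",
              x$full, x$reduced, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
print.ror_model <- function(x, digits = 4, ...) {
  cat("Cross-validated linear model of irAE reporting odds ratio\n")
  terms <- sprintf("%.4g x %s", x$coefficients[-1], x$predictors)
  ic <- x$coefficients[1]
  cat(sprintf("  ROR = %s%s\n",
              if (length(terms)) paste(terms, collapse = " + ") else "",
              sprintf(" %s %.4g", if (ic < 0) "-" else "+", abs(ic))))
  if (!is.null(x$loocv_r))
    cat(sprintf("  LOOCV R = %.3f (p = %.3g), unexplained variance = %.3f\n",
                x$loocv_r, x$loocv_p, x$unexplained_variance))
  if (!is.null(x$vif))
    cat(sprintf("  max VIF = %.2f%s\n", max(x$vif),
                if (attr(x$vif, "flagged")) " (collinearity flagged)" else ""))
  cat(sprintf("  n = %d cancer types\n", x$n))
  invisible(x)
}

#' @export
coef.ror_model <- function(object, ...) object$coefficients

#' @export
residuals.ror_model <- function(object, ...) object$residuals

#' @export
fitted.ror_model <- function(object, ...) object$fitted

#' @export
logLik.ror_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' Predict the ROR for external factor values
#'
#' Applies the full-data coefficients (not the LOOCV folds) to new factor
#' values, e.g. the factor medians of a cancer type outside the training
#' panel.
#'
#' @param object a `ror_model`.
#' @param newdata data.frame, named list, or named numeric vector providing
#'   every model predictor.
#' @param ... unused.
#' @return numeric vector of predicted RORs.
#' @export
predict.ror_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss))
    stop_input("missing predictor(s) in newdata: %s",
               paste(miss, collapse = ", "))
  X <- build_design(newdata, object$predictors)
  drop(X %*% object$coefficients)
}

#' @export
summary.ror_model <- function(object, ...) {
  structure(list(model = object,
                 coef_table = cbind(estimate = object$coefficients,
                                    se = object$se_coef),
                 loocv_r = object$loocv_r,
                 loocv_p = object$loocv_p,
                 unexplained_variance = object$unexplained_variance,
                 vif = object$vif, n = object$n),
            class = "summary.ror_model")
}

#' @export
print.summary.ror_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' @export
plot.ror_model <- function(x, ...) {
  if (is.null(x$loocv_pred))
    stop_input("model was fitted with loocv = FALSE")
  graphics::plot(x$loocv_pred, x$y,
                 xlab = "LOOCV-predicted ROR", ylab = "Observed ROR",
                 main = sprintf("LOOCV R = %.2f", x$loocv_r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.ror_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(max(object$rss / object$n, SIGMA2_FLOOR))
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(object$n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$units
  out
}
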