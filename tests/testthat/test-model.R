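test_that("full-data OLS matches an independent normal-equations solve", {
  # 5-point hand dataset
  df <- data.frame(ror = c(1.2, 2.1, 2.9, 4.2, 5.1),
                   x1 = c(0.1, 0.3, 0.4, 0.7, 0.8),
                   x2 = c(2.0, 1.0, 3.0, 2.5, 4.0))
  fit <- ror_model(ror ~ x1 + x2, df, loocv = FALSE)
  X <- cbind(1, df$x1, df$x2)
  expect_equal(unname(coef(fit)), oracle_ols(X, df$ror), tolerance = 1e-10)
  # log-likelihood equals the ML Gaussian form used by lm
  expect_equal(fit$loglik, as.numeric(logLik(lm(ror ~ x1 + x2, df))),
               tolerance = 1e-10)
  # intercept-only model fits the mean
  m0 <- ror_model(ror ~ 1, data.frame(ror = c(3, 3, 3, 3)), loocv = FALSE)
  expect_equal(unname(coef(m0)), 3)
})

test_that("perfect fits are floored and flagged, not infinite", {
  df <- data.frame(ror = 1:6, x = (1:6) * 2 + 1)
  fit <- ror_model(ror ~ x, df)
  expect_true(fit$degenerate)
  expect_true(is.finite(fit$loglik))
  expect_equal(fit$loocv_r, 1)
  expect_equal(fit$unexplained_variance, 0)
})

test_that("rank deficiency and tiny n raise classed errors", {
  df <- data.frame(ror = rnorm(6), x1 = 1:6, x2 = 2 * (1:6))
  expect_error(ror_model(ror ~ x1 + x2, df), class = "irae_degenerate_error")
  expect_error(ror_model(ror ~ x1, df[1:2, ]), class = "irae_degenerate_error")
  expect_error(ror_model(ror ~ nope, df), "nope")
})

test_that("LOOCV predictions equal refit-loop and leverage-identity oracles", {
  for (seed in 1:10) {
    fx <- random_fixture(seed)
    fit <- ror_model(reformulate(setdiff(names(fx$df), "ror"), "ror"), fx$df)
    expect_equal(fit$loocv_pred, oracle_loo_refit(fx$X, fx$y),
                 tolerance = 1e-10)
    expect_equal(fit$loocv_pred, oracle_loo_leverage(fx$X, fx$y),
                 tolerance = 1e-10)
  }
})

test_that("LOOCV r is near zero for pure noise and 1 for exact structure", {
  set.seed(14)
  rs <- replicate(60, {
    df <- data.frame(ror = rnorm(12), x = rnorm(12))
    ror_model(ror ~ x, df)$loocv_r
  })
  # held-out predictions of an uninformative model anticorrelate (the
  # well-known negative bias of cross-validated correlation under the null)
  expect_lt(mean(rs), 0)
  expect_gt(mean(rs), -0.65)
  df <- data.frame(ror = 1:8, x = 1:8)
  expect_equal(ror_model(ror ~ x, df)$loocv_r, 1)
})

test_that("VIF matches auxiliary regressions and flags collinearity", {
  # orthogonal centered predictors have VIF 1
  X <- cbind(x1 = c(-1, 1, -1, 1, 0), x2 = c(-1, -1, 1, 1, 0))
  v <- vif(X)
  expect_equal(as.vector(v), c(1, 1), tolerance = 1e-12)
  expect_false(attr(v, "flagged"))
  # duplicated predictor: infinite VIF, flagged, no exception
  dup <- cbind(x1 = rnorm(8), x2 = 0)
  dup[, 2] <- dup[, 1]
  vd <- vif(dup)
  expect_true(all(is.infinite(vd)))
  expect_true(attr(vd, "flagged"))
  # near-duplicate exceeds the conventional threshold of 4
  set.seed(2)
  x1 <- rnorm(20)
  near <- cbind(x1 = x1, x2 = x1 + rnorm(20, sd = 0.05))
  vn <- vif(near)
  expect_true(all(vn > 4))
  expect_equal(as.vector(vn), oracle_vif(near), tolerance = 1e-10)
  # random fixtures against the auxiliary-regression oracle
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 3), 12, 3)
    expect_equal(as.vector(vif(X)), oracle_vif(X), tolerance = 1e-10)
  }
})

test_that("VIF agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(7)
  df <- data.frame(y = rnorm(15), a = rnorm(15), b = rnorm(15), c = rnorm(15))
  df$b <- df$a * 0.8 + df$b * 0.6
  ours <- vif(as.matrix(df[, c("a", "b", "c")]))
  ref <- car::vif(lm(y ~ a + b + c, df))
  expect_equal(as.vector(ours), unname(ref[c("a", "b", "c")]), tolerance = 1e-8)
})

test_that("LR test matches two explicit fits and the lmtest reference", {
  # hand 6-point dataset
  df <- data.frame(ror = c(1, 2.2, 2.8, 4.1, 5.2, 5.8),
                   x1 = c(0.2, 0.4, 0.5, 0.9, 1.1, 1.2),
                   x2 = c(1, 0, 1, 0, 1, 0))
  full <- ror_model(ror ~ x1 + x2, df, loocv = FALSE)
  red <- ror_model(ror ~ x1, df, loocv = FALSE)
  out <- lr_test(full, red)
  lam_oracle <- 2 * (oracle_loglik(cbind(1, df$x1, df$x2), df$ror) -
                       oracle_loglik(cbind(1, df$x1), df$ror))
  expect_equal(out$statistic, lam_oracle, tolerance = 1e-10)
  expect_equal(out$p.value, pchisq(lam_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  skip_if_not_installed("lmtest")
  ref <- lmtest::lrtest(lm(ror ~ x1 + x2, df), lm(ror ~ x1, df))
  expect_equal(out$statistic, abs(ref$Chisq[2]), tolerance = 1e-8)
  expect_equal(out$p.value, ref$`Pr(>Chisq)`[2], tolerance = 1e-8)
})

test_that("LR statistic is nonnegative and zero for an irrelevant predictor", {
  for (seed in 1:10) {
    fx <- random_fixture(seed, n = 12, p = 2)
    full <- ror_model(ror ~ x1 + x2, fx$df, loocv = FALSE)
    red <- ror_model(ror ~ x1, fx$df, loocv = FALSE)
    expect_gte(lr_test(full, red)$statistic, 0)
  }
  # a predictor orthogonal to the response and co-predictor adds nothing
  df <- data.frame(ror = c(1, 2, 1, 2), x1 = c(0, 0, 1, 1))
  df$x2 <- c(-1, 1, 1, -1)       # orthogonal to intercept, x1 and y
  full <- ror_model(ror ~ x1 + x2, df, loocv = FALSE)
  red <- ror_model(ror ~ x1, df, loocv = FALSE)
  out <- lr_test(full, red)
  expect_equal(out$statistic, 0, tolerance = 1e-7)
  expect_equal(out$p.value, 1, tolerance = 1e-4)
  expect_error(lr_test(red, full), class = "irae_input_error")
})

test_that("external prediction applies full-data coefficients", {
  # coefficients printed for the naiveCD4T + log(TMB) bivariate model
  fit <- structure(list(predictors = c("naiveCD4T", "log_TMB"),
                        coefficients = c(`(Intercept)` = -2.09,
                                         naiveCD4T = 24.41, log_TMB = 1.01)),
                   class = "ror_model")
  pred <- predict(fit, c(naiveCD4T = 0.1, log_TMB = 1))
  expect_equal(pred, 24.41 * 0.1 + 1.01 * 1 - 2.09)  # 0.362
  expect_equal(predict(fit, c(naiveCD4T = 0, log_TMB = 0)), -2.09)
  # linearity in the inputs
  p0 <- predict(fit, c(naiveCD4T = 0, log_TMB = 0))
  p1 <- predict(fit, c(naiveCD4T = 0.2, log_TMB = 2))
  p2 <- predict(fit, c(naiveCD4T = 0.4, log_TMB = 4))
  expect_equal(p2 - p0, 2 * (p1 - p0), tolerance = 1e-12)
  expect_error(predict(fit, c(naiveCD4T = 0.1)), "log_TMB")
})

test_that("model methods expose coefficients, residuals and simulation", {
  fx <- random_fixture(3, n = 10, p = 2)
  fit <- ror_model(ror ~ x1 + x2, fx$df)
  expect_equal(fitted(fit) + residuals(fit), fx$y, ignore_attr = TRUE)
  expect_output(print(fit), "LOOCV R")
  expect_output(print(summary(fit)), "Coefficients")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(10L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})
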