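# Independent oracles used across the suite. These deliberately re-derive
# every statistic from first principles, sharing no code with the package.

# Brute-force per-cancer-type ROR recount on a small report table.
oracle_ror_recount <- function(reports, term_vec) {
  norm <- function(v) gsub("[[:space:]]+", " ", tolower(trimws(v)))
  terms <- norm(term_vec)
  irae <- vapply(strsplit(reports$reactions, ";", fixed = TRUE),
                 function(r) any(norm(r) %in% terms), logical(1))
  types <- unique(reports$indication)
  out <- lapply(types, function(k) {
    a <- sum(irae & reports$indication == k)
    b <- sum(!irae & reports$indication == k)
    cc <- sum(irae & reports$indication != k)
    d <- sum(!irae & reports$indication != k)
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    data.frame(cancer_type = k,
               ror = (cells[1] * cells[4]) / (cells[2] * cells[3]))
  })
  do.call(rbind, out)
}

# Exhaustive-enumeration Mann-Whitney oracle (no ties assumed).
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); n <- length(pool)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  labelings <- utils::combn(n, n1)
  u_all <- apply(labelings, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p <- if (u_obs > n1 * (n - n1) / 2) mean(u_all >= u_obs) else
    mean(u_all <= u_obs)
  list(U = u_obs, p = min(1, 2 * p))
}

# Hand-written Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# Normal-equations OLS solve (intercept included in X).
oracle_ols <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Closed-form leave-one-out predictions via the leverage identity.
oracle_loo_leverage <- function(X, y) {
  H <- X %*% solve(crossprod(X)) %*% t(X)
  resid <- y - H %*% y
  drop(y - resid / (1 - diag(H)))
}

# Explicit per-fold LOO refit loop.
oracle_loo_refit <- function(X, y) {
  vapply(seq_along(y), function(i) {
    cf <- solve(crossprod(X[-i, , drop = FALSE]),
                crossprod(X[-i, , drop = FALSE], y[-i]))
    drop(X[i, , drop = FALSE] %*% cf)
  }, numeric(1))
}

# Auxiliary-regression VIF oracle.
oracle_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}

# ML Gaussian log-likelihood of an lm-style fit, for LR-test oracles.
oracle_loglik <- function(X, y) {
  cf <- oracle_ols(X, y)
  rss <- sum((y - X %*% cf)^2)
  n <- length(y)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

# Small random report table with known vocabulary.
random_report_table <- function(seed) {
  set.seed(seed)
  irae_terms <- c("colitis", "pneumonitis", "hypophysitis")
  other_terms <- c("nausea", "headache", "fatigue", "anaemia")
  n_types <- sample(3:5, 1)
  types <- paste0("T", seq_len(n_types))
  n <- sample(30:80, 1)
  reactions <- vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    paste(sample(c(irae_terms, other_terms), k), collapse = ";")
  }, character(1))
  list(reports = data.frame(report_id = sprintf("r%03d", seq_len(n)),
                            drugs = "nivolumab",
                            indication = sample(types, n, replace = TRUE),
                            reactions = reactions,
                            stringsAsFactors = FALSE),
       terms = irae_terms)
}

# Random well-conditioned regression fixture (n x p, intercept prepended).
random_fixture <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(8:15, 1)
  if (is.null(p)) p <- sample(1:3, 1)
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
  y <- drop(X %*% runif(p + 1, -2, 2)) + rnorm(n)
  list(X = X, y = y,
       df = setNames(as.data.frame(cbind(y, X[, -1, drop = FALSE])),
                     c("ror", paste0("x", seq_len(p)))))
}

# Vectors with an exactly prescribed Pearson correlation.
make_correlated <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x))
  x <- as.numeric(scale(x)); e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
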