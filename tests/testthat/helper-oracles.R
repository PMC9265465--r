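# Independent brute-force oracles used to freeze expected values. These are
# deliberately written as plain loops, separate from the package's vectorized
# implementations.

# entropy-weight composite pipeline, monolithic loop version
oracle_composite <- function(values, low = 1, high = 9) {
  m <- nrow(values)
  n <- ncol(values)
  P <- matrix(0, m, n)
  for (j in 1:n) for (i in 1:m) P[i, j] <- values[i, j] / sum(values[, j])
  e <- numeric(n)
  for (j in 1:n) {
    acc <- 0
    for (i in 1:m) if (P[i, j] > 0) acc <- acc + P[i, j] * log(P[i, j])
    e[j] <- -acc / log(m)
  }
  w <- (1 - e) / sum(1 - e)
  a <- matrix(0, m, n)
  for (j in 1:n) {
    vmin <- min(values[, j]); vmax <- max(values[, j])
    for (i in 1:m) a[i, j] <- low + (values[i, j] - vmin) * (high - low) / (vmax - vmin)
  }
  b <- numeric(m)
  for (i in 1:m) b[i] <- sum(w * a[i, ])
  list(P = P, e = e, w = w, a = a, b = b)
}

# loop-based external predictive r-squared
oracle_r2pred <- function(y, yhat, mu) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + (y[i] - yhat[i])^2
    den <- den + (y[i] - mu)^2
  }
  1 - num / den
}

# leave-one-out q2 for p = 1 by explicit simple-regression folds (PLS with
# one component on a single descriptor is simple linear regression)
oracle_loo_q2_univariate <- function(x, y) {
  n <- length(y)
  press <- 0
  for (i in 1:n) {
    xt <- x[-i]; yt <- y[-i]
    b <- sum((xt - mean(xt)) * (yt - mean(yt))) / sum((xt - mean(xt))^2)
    a <- mean(yt) - b * mean(xt)
    press <- press + (y[i] - (a + b * x[i]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# factorial effects as 2x the coefficients of a least-squares fit on
# -1/+1-coded regressors with all interactions
oracle_effects_lm <- function(design, response = "energy") {
  factors <- setdiff(names(design), c("group", response))
  coded <- as.data.frame(2 * as.matrix(design[, factors]) - 1)
  dat <- cbind(coded, .y = design[[response]])
  form <- stats::as.formula(
    paste(".y ~ (", paste(factors, collapse = " + "), ")^", length(factors)))
  cf <- coef(lm(form, data = dat))[-1]
  names(cf) <- gsub("`", "", names(cf))
  2 * cf
}

fixture <- function(name) read.csv(fq_example(name), check.names = FALSE)

# seeded response permutation for null-model simulations
with_seed_perm <- function(y, seed) {
  set.seed(seed + 10000L)
  sample(y)
}
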