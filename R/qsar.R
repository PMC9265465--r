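#' Fit a PLS regression model (NIPALS, single response)
#'
#' Partial least squares regression as used in CoMFA-style 3D-QSAR:
#' descriptors are column-centered and the response centered; columns are
#' not variance-scaled by default (molecular-field blocks carry meaningful
#' relative magnitudes), with an optional autoscaling flag. Components are
#' extracted by the NIPALS algorithm, which is fully deterministic:
#' identical inputs give bit-identical fits. If the descriptor matrix runs
#' out of rank before `n_components`, extraction stops early and the model
#' records the number actually extracted.
#'
#' @param X numeric s x p descriptor matrix (no missing values).
#' @param y numeric response vector of length s.
#' @param n_components number of latent components to extract.
#' @param scale logical; autoscale columns to unit variance (default FALSE).
#' @return an object of class `"pls_model"` with weights `W`, loadings `P`,
#'   response loadings `q`, scores `T`, per-component regression coefficient
#'   matrix `coefficients` (p x A, column a = coefficients using components
#'   1..a), centers, and `n_components` actually extracted.
#' @export
fit_pls <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  s <- nrow(X)
  p <- ncol(X)
  if (length(y) != s) stop_fq("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop_fq("X and y must be finite with no missing values")
  }
  if (s < 3L) stop_fq("at least 3 samples are required")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(s - 1L, p)) {
    stop_fq("`n_components` must lie in 1..min(s-1, p)")
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2L, x_center)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(Xc, 2L, stats::sd)
    x_scale[x_scale < .Machine$double.eps] <- 1
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  yc <- y - y_center

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, s, n_components)
  q <- numeric(n_components)
  Xa <- Xc
  ya <- yc
  tol <- .Machine$double.eps^0.75 * max(1, sum(Xc^2))
  a <- 0L
  while (a < n_components) {
    w <- drop(crossprod(Xa, ya))
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn^2 <= tol) break  # residual X carries no covariance
    w <- w / wn
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt <= tol) break
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    a <- a + 1L
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  if (a == 0L) stop_fq("no PLS component could be extracted (X'y is null)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]

  # coefficients for each truncation 1..a: B_k = W_k (P_k' W_k)^-1 q_k
  coefs <- matrix(0, p, a)
  for (k in seq_len(a)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    R <- Wk %*% solve(crossprod(Pk, Wk))
    coefs[, k] <- R %*% q[seq_len(k)] / x_scale
  }
  structure(list(
    n_components = a,
    requested_components = n_components,
    W = W, P = P, q = q, scores = Tm,
    coefficients = coefs,
    x_center = x_center, y_center = y_center, x_scale = x_scale,
    scaled = scale
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s) over %d descriptor(s)%s\n",
              x$n_components, nrow(x$coefficients),
              if (x$n_components < x$requested_components)
                sprintf(" (stopped early; %d requested)", x$requested_components)
              else ""))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `"pls_model"`.
#' @param newdata numeric matrix with the same descriptor columns as the
#'   training matrix.
#' @param n_components number of components to use (default: all extracted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = object$n_components,
                              ...) {
  newdata <- as.matrix(newdata)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > object$n_components) {
    stop_fq("`n_components` exceeds the number extracted")
  }
  Xc <- sweep(newdata, 2L, object$x_center)
  drop(Xc %*% object$coefficients[, n_components]) + object$y_center
}

# internal: training r-squared at a given number of components
training_r2 <- function(model, X, y, n_components = model$n_components) {
  yhat <- predict(model, X, n_components)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated q-squared
#'
#' For each training sample in turn, a PLS model is refit without it and the
#' held-out response predicted; `q2 = 1 - PRESS / sum((y - mean(y))^2)`,
#' where the denominator uses the full training-set mean (fixed across
#' folds). q2 is at most 1 and may be negative when the model predicts worse
#' than the mean.
#'
#' @inheritParams fit_pls
#' @return scalar q-squared.
#' @export
loo_q2 <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  s <- nrow(X)
  if (s < 3L) stop_fq("leave-one-out needs at least 3 samples")
  ss <- sum((y - mean(y))^2)
  if (ss <= 0) stop_fq("constant response: q2 denominator is zero")
  press <- 0
  for (i in seq_len(s)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components, scale = scale)
    pred <- predict(fit, X[i, , drop = FALSE],
                    n_components = min(n_components, fit$n_components))
    press <- press + (y[i] - pred)^2
  }
  1 - press / ss
}

#' Choose the number of PLS components by leave-one-out q-squared
#'
#' Scans 1..`max_n` components and returns the most parsimonious count
#' whose q2 reaches the maximum: plateaus are resolved toward the smaller
#' model. `plateau_tol` sets what counts as a plateau — q2 gains below it
#' are treated as ties, the conventional guard against creeping a component
#' count upward on sub-noise-level improvements (exact ties are covered by
#' `plateau_tol = 0`).
#'
#' @inheritParams fit_pls
#' @param max_n largest component count to consider; capped at
#'   `min(max_n, s - 2, p)`.
#' @param plateau_tol q2 difference below which two component counts are
#'   tied (default 0.001).
#' @return list with `n_opt`, `q2` (at `n_opt`), and `q2_by_n`.
#' @export
select_components <- function(X, y, max_n, scale = FALSE, plateau_tol = 1e-3) {
  max_n <- as.integer(max_n)
  if (max_n < 1L) stop_fq("`max_n` must be at least 1")
  cap <- min(max_n, nrow(as.matrix(X)) - 2L, ncol(as.matrix(X)))
  q2s <- vapply(seq_len(cap), function(k) loo_q2(X, y, k, scale = scale),
                numeric(1))
  n_opt <- min(which(q2s >= max(q2s) - plateau_tol))
  list(n_opt = n_opt, q2 = q2s[n_opt], q2_by_n = q2s)
}

#' External predictive r-squared
#'
#' `r2pred = 1 - sum((y - yhat)^2) / sum((y - ref_mean)^2)` over the test
#' set, where `ref_mean` is conventionally the training-set response mean.
#'
#' @param y_test observed test responses.
#' @param y_hat_test predicted test responses.
#' @param reference_mean scalar reference mean for the denominator.
#' @return scalar r2pred (at most 1).
#' @export
r2pred <- function(y_test, y_hat_test, reference_mean) {
  if (length(y_test) < 1L || length(y_test) != length(y_hat_test)) {
    stop_fq("test observations and predictions must be non-empty and equal length")
  }
  check_number(reference_mean, "reference_mean")
  denom <- sum((y_test - reference_mean)^2)
  if (denom <= 0) stop_fq("r2pred denominator is zero")
  1 - sum((y_test - y_hat_test)^2) / denom
}

#' Overfit index of a QSAR model
#'
#' The relative gap between fitted and cross-validated determination,
#' `(r2 - q2) / r2`; values below 30% are conventionally read as not
#' overfitted.
#'
#' @param r2 training coefficient of determination (must be > 0).
#' @param q2 leave-one-out q-squared.
#' @return scalar fraction.
#' @export
#' @examples
#' overfit_index(0.984, 0.765)  # 0.2226
overfit_index <- function(r2, q2) {
  check_number(r2, "r2")
  check_number(q2, "q2")
  if (r2 <= 0) stop_fq("overfit index undefined for r2 <= 0")
  (r2 - q2) / r2
}

#' Build a full QSAR validation report
#'
#' Fits PLS on the training set with the leave-one-out-optimal number of
#' components, computes internal validation statistics (q2, training r2,
#' overfit index) and, when a test set is supplied, the external r2pred.
#' Pass/fail flags use the conventional strict thresholds q2 > 0.5,
#' r2 > 0.8, overfit index < 0.30, r2pred > 0.6.
#'
#' @param X_train,y_train training descriptors and responses.
#' @param X_test,y_test optional external test set (`NULL` for internal-only
#'   validation).
#' @param max_components cap on the component scan; the effective cap is
#'   `min(max_components, s_train - 2, p)` (default 10).
#' @param ref_mean reference mean convention for r2pred: `"train"` (default,
#'   the standard external-validation convention) or `"test"`.
#' @param scale autoscale descriptor columns (default FALSE).
#' @return an object of class `"qsar_report"`: list with `n_opt`, `q2`,
#'   `r2`, `overfit`, `r2pred` (NA when no test set), logical flags
#'   `q2_ok`, `r2_ok`, `overfit_ok`, `r2pred_ok`, the fitted `model`, and
#'   the `ref_mean` convention used.
#' @export
qsar_report <- function(X_train, y_train, X_test = NULL, y_test = NULL,
                        max_components = 10, ref_mean = c("train", "test"),
                        scale = FALSE) {
  ref_mean <- match.arg(ref_mean)
  X_train <- as.matrix(X_train)
  sel <- select_components(X_train, y_train, max_components, scale = scale)
  model <- fit_pls(X_train, y_train, sel$n_opt, scale = scale)
  r2 <- training_r2(model, X_train, y_train)
  ov <- overfit_index(r2, sel$q2)
  rp <- NA_real_
  if (!is.null(X_test)) {
    if (is.null(y_test)) stop_fq("`y_test` required with `X_test`")
    yhat <- predict(model, as.matrix(X_test))
    mu <- if (ref_mean == "train") mean(y_train) else mean(y_test)
    rp <- r2pred(y_test, yhat, mu)
  }
  structure(list(
    n_opt = sel$n_opt, q2 = sel$q2, r2 = r2, overfit = ov, r2pred = rp,
    q2_ok = sel$q2 > 0.5, r2_ok = r2 > 0.8, overfit_ok = ov < 0.30,
    r2pred_ok = if (is.na(rp)) NA else rp > 0.6,
    q2_by_n = sel$q2_by_n, ref_mean = ref_mean, model = model
  ), class = "qsar_report")
}

#' @export
print.qsar_report <- function(x, ...) {
  flag <- function(ok) if (is.na(ok)) "absent" else if (ok) "pass" else "FAIL"
  cat("3D-QSAR validation report\n")
  cat(sprintf("  components (n_opt): %d\n", x$n_opt))
  cat(sprintf("  q2  (LOO)        : %.4f  [> 0.5: %s]\n", x$q2, flag(x$q2_ok)))
  cat(sprintf("  r2  (training)   : %.4f  [> 0.8: %s]\n", x$r2, flag(x$r2_ok)))
  cat(sprintf("  (r2 - q2)/r2     : %.2f%%  [< 30%%: %s]\n",
              100 * x$overfit, flag(x$overfit_ok)))
  if (is.na(x$r2pred)) {
    cat("  r2pred           : absent (no external test set)\n")
  } else {
    cat(sprintf("  r2pred (%s mean): %.4f  [> 0.6: %s]\n",
                x$ref_mean, x$r2pred, flag(x$r2pred_ok)))
  }
  invisible(x)
}
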