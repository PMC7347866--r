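#' Fit a vector autoregressive model to one window
#'
#' Least-squares VAR(p) fit of the three-channel feature series:
#' `x_t = c + A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`, with the residual
#' covariance estimated from the one-step residuals (maximum-likelihood
#' denominator). A rank-deficient regressor matrix falls back to a ridge
#' solve with jitter `1e-6 * mean diagonal` of the normal equations.
#'
#' @param feature A `feature_vector` (or `window_matrix`) to model.
#' @param order Autoregressive order `p` (>= 1).
#' @param warn Warn when the ridge fallback engages.
#' @return A `dynamics_model`: coefficient matrices `A` (list of 3x3),
#'   `intercept`, residual covariance `Sigma`, `order`, `channels`, and the
#'   source window reference.
#' @export
fit_var <- function(feature, order = 2, warn = TRUE) {
  X <- feature$values
  p <- as.integer(order)
  stopifnot(p >= 1)
  n <- nrow(X)
  d <- ncol(X)
  if (n <= p + 1) stopf("window too short (%d) for VAR(%d)", n, p)
  Y <- X[(p + 1):n, , drop = FALSE]
  Z <- cbind(1, do.call(cbind, lapply(seq_len(p), function(l)
    X[(p + 1 - l):(n - l), , drop = FALSE])))
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z) || nrow(Z) < ncol(Z)) {
    if (warn) warnf("rank-deficient VAR regressors; using ridge fallback")
    G <- crossprod(Z)
    lam <- 1e-6 * mean(diag(G))
    if (lam <= 0) lam <- 1e-6
    B <- solve(G + lam * diag(ncol(Z)), crossprod(Z, Y))
  } else {
    B <- qr.coef(qrZ, Y)
  }
  resid <- Y - Z %*% B
  Sigma <- crossprod(resid) / nrow(Y)
  Sigma <- (Sigma + t(Sigma)) / 2
  A <- lapply(seq_len(p), function(l)
    t(B[(2 + (l - 1) * d):(1 + l * d), , drop = FALSE]))
  structure(list(A = A, intercept = as.numeric(B[1, ]), Sigma = Sigma,
                 order = p, channels = colnames(X) %||% CHANNELS,
                 source = list(session_id = feature$window$session_id %||% NA,
                               start_minute = feature$window$start_minute %||% NA)),
            class = "dynamics_model")
}

# One-step-ahead conditional means of `model` over the rows of X
# (a T x 3 matrix); returns a (T - p) x 3 matrix aligned with rows p+1..T.
var_predict <- function(model, X) {
  p <- model$order
  n <- nrow(X)
  mu <- matrix(rep(model$intercept, each = n - p), n - p)
  for (l in seq_len(p))
    mu <- mu + X[(p + 1 - l):(n - l), , drop = FALSE] %*% t(model$A[[l]])
  mu
}

#' One-step residuals of a dynamics model on a window
#'
#' Residuals `x_t - prediction(x_{t-1..t-p})` across the window, and their
#' mean squared norm, used to characterise how well a model explains a
#' stretch of data.
#'
#' @param model A `dynamics_model`.
#' @param window A `window_matrix` or `feature_vector`.
#' @return List with `residuals` (matrix) and `msr` (mean squared residual).
#' @export
one_step_residuals <- function(model, window) {
  X <- window$values
  if (nrow(X) <= model$order)
    stopf("window length must exceed the model order")
  R <- X[(model$order + 1):nrow(X), , drop = FALSE] - var_predict(model, X)
  list(residuals = R, msr = mean(rowSums(R^2)))
}

regularize_sigma <- function(Sigma, warn = TRUE) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev), 1)) {
    if (warn) warnf("singular residual covariance; adding jitter")
    Sigma <- Sigma + (1e-6 * sum(diag(Sigma)) / nrow(Sigma) + 1e-10) *
      diag(nrow(Sigma))
  }
  Sigma
}

# KL(N(mu1, S1) || N(mu2, S2)) averaged over rows of mu1/mu2.
gauss_kl <- function(mu1, S1, mu2, S2) {
  d <- ncol(S1)
  ch2 <- chol(S2)
  S2inv <- chol2inv(ch2)
  logdet2 <- 2 * sum(log(diag(ch2)))
  logdet1 <- 2 * sum(log(diag(chol(S1))))
  delta <- mu2 - mu1
  quad <- mean(rowSums((delta %*% S2inv) * delta))
  0.5 * (sum(S2inv * S1) + quad - d + logdet2 - logdet1)
}

#' Dissimilarity between two dynamics models
#'
#' The symmetrised Kullback-Leibler divergence
#' `0.5 * (KL(N1 || N2) + KL(N2 || N1))` between the models' Gaussian
#' one-step predictive distributions, averaged over a shared set of
#' reference windows. Non-negative, symmetric and zero for identical
#' models; the triangle inequality is not claimed (symmetrised KL is a
#' pseudo-metric here, not a metric). A coefficient-space alternative
#' (`kind = "coeff_frobenius"`) ignores the reference windows.
#'
#' @param m1,m2 `dynamics_model` objects with matching order and channels.
#' @param reference_windows List of `window_matrix`/`feature_vector`
#'   objects on the models' feature scale.
#' @param kind `"symkl"` (default) or `"coeff_frobenius"`.
#' @param warn Warn on covariance regularization.
#' @return Non-negative scalar.
#' @export
model_dissimilarity <- function(m1, m2, reference_windows = NULL,
                                kind = c("symkl", "coeff_frobenius"),
                                warn = TRUE) {
  kind <- match.arg(kind)
  stopifnot(m1$order == m2$order)
  if (kind == "coeff_frobenius") {
    dA <- sum(vapply(seq_along(m1$A), function(l)
      sum((m1$A[[l]] - m2$A[[l]])^2), numeric(1)))
    return(sqrt(dA + sum((m1$intercept - m2$intercept)^2) +
                  sum((m1$Sigma - m2$Sigma)^2)))
  }
  if (is.null(reference_windows) || !length(reference_windows))
    stopf("symkl dissimilarity needs at least one reference window")
  S1 <- regularize_sigma(m1$Sigma, warn)
  S2 <- regularize_sigma(m2$Sigma, warn)
  vals <- vapply(reference_windows, function(w) {
    X <- w$values
    mu1 <- var_predict(m1, X)
    mu2 <- var_predict(m2, X)
    0.5 * (gauss_kl(mu1, S1, mu2, S2) + gauss_kl(mu2, S2, mu1, S1))
  }, numeric(1))
  max(mean(vals), 0)
}

#' Pairwise dissimilarity matrix over a set of models
#'
#' @param models List of `dynamics_model` objects.
#' @param reference_windows Shared reference windows (see
#'   [model_dissimilarity()]).
#' @inheritParams model_dissimilarity
#' @return Symmetric non-negative matrix with zero diagonal, class
#'   `dissimilarity_matrix`.
#' @export
build_dissimilarity_matrix <- function(models, reference_windows = NULL,
                                       kind = "symkl", warn = FALSE) {
  n <- length(models)
  if (n < 2) stopf("need at least 2 models")
  D <- matrix(0, n, n)
  ids <- vapply(seq_len(n), function(i)
    paste0(models[[i]]$source$session_id, "@", models[[i]]$source$start_minute),
    character(1))
  dimnames(D) <- list(ids, ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <-
      model_dissimilarity(models[[i]], models[[j]], reference_windows,
                          kind = kind, warn = warn)
  }
  structure(D, class = c("dissimilarity_matrix", "matrix"))
}
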