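#' Flatten a dynamics model into a descriptor vector
#'
#' Concatenates the coefficient matrices, the intercept and the
#' lower-triangular Cholesky factor of the residual covariance (positive
#' diagonal convention, so the mapping is injective on valid models). For
#' three channels and order `p` the descriptor has length `9p + 3 + 6`.
#'
#' @param model A `dynamics_model`.
#' @return Numeric descriptor vector.
#' @export
model_descriptor <- function(model) {
  S <- model$Sigma
  L <- tryCatch(t(chol(S)), error = function(e)
    t(chol(S + (1e-10 + 1e-8 * sum(diag(S)) / nrow(S)) * diag(nrow(S)))))
  c(unlist(lapply(model$A, as.numeric)),
    model$intercept,
    L[lower.tri(L, diag = TRUE)])
}

ns_phi <- function(U, centres, sigma) {
  # Gaussian RBF design matrix with a bias column
  d2 <- outer(rowSums(U^2), rowSums(centres^2), "+") -
    2 * U %*% t(centres)
  cbind(1, exp(-pmax(d2, 0) / (2 * sigma^2)))
}

ns_stress <- function(Y, D) {
  dy <- as.matrix(stats::dist(Y))
  sum(((D - dy)[upper.tri(D)])^2)
}

# Gradient of the Sammon-type stress with respect to the projections Y.
ns_stress_grad <- function(Y, D) {
  dy <- as.matrix(stats::dist(Y))
  W <- matrix(0, nrow(Y), nrow(Y))
  nz <- dy > 1e-12
  W[nz] <- 2 * (dy[nz] - D[nz]) / dy[nz]
  diag(W) <- 0
  (rowSums(W) * Y) - W %*% Y
}

#' Train a NeuroScale-style topographic projection
#'
#' Fits a radial-basis-function network from (standardized) model
#' descriptors to two dimensions by minimising the Sammon-type stress
#' `sum_(i<j) (d_ij - yhat_ij)^2`, where `d_ij` is the supplied model
#' dissimilarity and `yhat_ij` the Euclidean distance between projections.
#' Training uses a shadow-targets style gradient step on the output
#' weights with a backtracking step size, so the stress is non-increasing
#' across iterations; the initial configuration is classical metric
#' scaling of the dissimilarities. Deterministic given the seed (used for
#' the k-means basis centres).
#'
#' @param descriptors Numeric matrix, one row per model.
#' @param dissim Symmetric non-negative dissimilarity matrix.
#' @param n_centres Number of RBF centres (capped at `n`).
#' @param max_iter,tol Optimiser budget and relative stress tolerance.
#' @param seed Integer seed.
#' @return Object of class `neuroscale_map` with the basis, output weights,
#'   standardization statistics, final `stress`, the per-iteration
#'   `stress_trace`, and the training projections `Y`.
#' @export
train_neuroscale <- function(descriptors, dissim, n_centres = 50,
                             max_iter = 2000, tol = 1e-6, seed = 1) {
  X <- as.matrix(descriptors)
  D <- unclass(as.matrix(dissim))
  n <- nrow(X)
  if (n < 4) stopf("need at least 4 descriptors to train a projection")
  if (!all(is.finite(D))) stopf("dissimilarities must be finite")
  stopifnot(nrow(D) == n, ncol(D) == n)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  U <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  m <- min(n_centres, n)
  centres <- if (m == n) U else
    with_seed(seed, stats::kmeans(U, m, nstart = 5, iter.max = 50)$centers)
  dc <- stats::dist(centres)
  sigma <- stats::median(dc[dc > 0])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1

  Phi <- ns_phi(U, centres, sigma)
  ridge <- 1e-8 * diag(ncol(Phi))

  Y0 <- stats::cmdscale(D, k = 2)
  if (ncol(Y0) < 2) Y0 <- cbind(Y0, 0)[, 1:2, drop = FALSE]
  W <- solve(crossprod(Phi) + ridge, crossprod(Phi, Y0))

  Y <- Phi %*% W
  S <- ns_stress(Y, D)
  trace <- S
  eta <- 1e-3 / max(S, 1e-12)
  for (it in seq_len(max_iter)) {
    G <- crossprod(Phi, ns_stress_grad(Y, D))
    accepted <- FALSE
    for (bt in 1:40) {
      W2 <- W - eta * G
      Y2 <- Phi %*% W2
      S2 <- ns_stress(Y2, D)
      if (S2 <= S) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    improve <- (S - S2) / max(S, 1e-12)
    W <- W2; Y <- Y2; S <- S2
    trace <- c(trace, S)
    eta <- eta * 1.2
    if (improve < tol) break
  }

  structure(list(centres = centres, sigma = sigma, W = W,
                 mean = mu, sd = sdv,
                 stress = S, stress_trace = trace,
                 Y = Y, n_train = n, seed = seed),
            class = "neuroscale_map")
}

#' @export
print.neuroscale_map <- function(x, ...) {
  cat(sprintf("<neuroscale_map> %d training points, %d centres, stress %.4g (%d iterations)\n",
              x$n_train, nrow(x$centres), x$stress, length(x$stress_trace)))
  invisible(x)
}

#' Project descriptors through a trained map
#'
#' @param object A `neuroscale_map`.
#' @param newdata Descriptor vector or matrix (rows = items).
#' @param ... Unused.
#' @return An `n x 2` matrix of projections.
#' @export
predict.neuroscale_map <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  if (ncol(X) != length(object$mean))
    stopf("descriptor dimension %d does not match map dimension %d",
          ncol(X), length(object$mean))
  U <- sweep(sweep(X, 2, object$mean), 2, object$sd, "/")
  ns_phi(U, object$centres, object$sigma) %*% object$W
}

#' Local metric and magnification of the projection map
#'
#' The Jacobian `J = dy/dx` of the map at a descriptor gives the local
#' metric `G = J J^T` (2 x 2, symmetric positive semi-definite) and the
#' magnification factor `sqrt(det G)`: the local area scaling of the
#' visualisation space, used as its operational local curvature. Computed
#' analytically from the RBF derivatives (the bias column contributes
#' nothing).
#'
#' @param map A `neuroscale_map`.
#' @param descriptor Numeric descriptor vector.
#' @return List with `G`, `magnification` and the `2 x d` `jacobian`.
#' @export
local_metric <- function(map, descriptor) {
  x <- as.numeric(descriptor)
  if (length(x) != length(map$mean))
    stopf("descriptor dimension %d does not match map dimension %d",
          length(x), length(map$mean))
  u <- (x - map$mean) / map$sd
  diffc <- sweep(map$centres, 2, u)          # m x d, c_j - u
  phi <- exp(-rowSums(diffc^2) / (2 * map$sigma^2))
  # d phi_j / d u = phi_j (c_j - u) / sigma^2 ; chain rule du/dx = 1/sd
  Dphi <- (phi / map$sigma^2) * diffc        # m x d
  Wr <- map$W[-1, , drop = FALSE]            # drop bias row
  J <- t(Wr) %*% Dphi                        # 2 x d (wrt u)
  J <- sweep(J, 2, map$sd, "/")              # wrt raw descriptor
  G <- J %*% t(J)
  list(G = G, magnification = sqrt(max(det(G), 0)), jacobian = J)
}

#' Serialize a trained map to JSON (and back)
#'
#' @param map A `neuroscale_map`.
#' @param path Output path.
#' @export
write_neuroscale <- function(map, path) {
  jsonlite::write_json(
    list(centres = map$centres, sigma = map$sigma, W = map$W,
         mean = map$mean, sd = map$sd, stress = map$stress,
         Y = map$Y, n_train = map$n_train, seed = map$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neuroscale
#' @export
read_neuroscale <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(centres = as.matrix(x$centres), sigma = x$sigma,
                 W = as.matrix(x$W), mean = as.numeric(x$mean),
                 sd = as.numeric(x$sd), stress = x$stress,
                 stress_trace = NULL, Y = as.matrix(x$Y),
                 n_train = x$n_train, seed = x$seed),
            class = "neuroscale_map")
}
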