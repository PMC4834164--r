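# RBF kernel, adaptive kernel width, and the case-weighted RBF C-SVC weak
# learner. Kernel matrices are assembled in R with BLAS; the dual is solved
# by the SMO routine in src/smo.cpp.

#' Gaussian (RBF) kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`.
#'
#' @param x,z Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, z, sigma) {
  assert_number(sigma, "sigma", lower = .Machine$double.xmin)
  if (length(x) != length(z)) {
    stopf("`x` and `z` must have equal length", class = "pharmboost_shape_error")
  }
  exp(-sum((x - z)^2) / (2 * sigma^2))
}

# Kernel matrix between the rows of X and Z.
rbf_kernel_matrix <- function(X, Z, sigma) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  d2 <- sq_dist_matrix(X, Z)
  exp(-d2 / (2 * sigma^2))
}

sq_dist_matrix <- function(X, Z) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  d2
}

#' Adaptive RBF width from a sample set
#'
#' The kernel width of each weak learner is tied to the dispersion of its
#' training set: the population standard deviation of all feature-matrix
#' entries pooled (default), or the mean of the per-feature population
#' standard deviations.
#'
#' @param x Feature matrix (or data frame of numeric columns).
#' @param pool `"pooled"` (one scalar over all entries) or
#'   `"per_feature_mean"`.
#' @param floor Lower clamp for degenerate (constant) matrices.
#' @return The width sigma.
#' @export
compute_sigma <- function(x, pool = c("pooled", "per_feature_mean"),
                          floor = 1e-12) {
  pool <- match.arg(pool)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 samples to compute sigma")
  sigma <- if (pool == "pooled") {
    sqrt(mean((x - mean(x))^2))
  } else {
    mean(apply(x, 2L, function(col) sqrt(mean((col - mean(col))^2))))
  }
  if (!is.finite(sigma) || sigma < floor) {
    warn(sprintf("degenerate sample set: sigma clamped to %g", floor))
    sigma <- floor
  }
  sigma
}

#' Train a case-weighted soft-margin RBF SVM
#'
#' Solves the C-SVC dual with per-sample misclassification costs
#' `C_i = cost * n * w_i`, where `w` are the (normalized) boosting weights of
#' the `n`-sample weight vector. With uniform weights this reduces to the
#' ordinary C-SVC with cost `cost`.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Labels, +1 (active pose) or -1 (decoy pose).
#' @param weights Per-sample weights; default uniform. Interpreted relative
#'   to `n_total`.
#' @param sigma RBF width; default [compute_sigma()] of `x`.
#' @param cost Soft-margin cost C (default 5).
#' @param n_total Size of the full weight vector the weights came from
#'   (defaults to `length(weights)`); lets a weight-trimmed subset keep the
#'   costs of the full-set weighting.
#' @return A `weighted_svm` model (support vectors, dual coefficients, bias,
#'   sigma, cost).
#' @export
train_weighted_svm <- function(x, y, weights = NULL, sigma = NULL, cost = 5,
                               n_total = NULL) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2L) {
    stopf("training requires both classes", class = "pharmboost_training_error")
  }
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stopf("invalid weight vector")
  }
  if (is.null(n_total)) n_total <- n
  if (is.null(sigma)) sigma <- compute_sigma(x)
  assert_number(sigma, "sigma", lower = .Machine$double.xmin)
  assert_number(cost, "cost", lower = .Machine$double.xmin)

  Ci <- cost * n_total * weights
  Ci <- pmax(Ci, 1e-10)  # zero-weight samples cannot carry dual mass anyway
  K <- rbf_kernel_matrix(x, x, sigma)
  sol <- smo_solve(K, y, Ci)

  sv <- which(sol$alpha > 1e-12)
  structure(list(sv_x = x[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * y[sv],
                 b = sol$b, sigma = sigma, cost = cost,
                 sv_index = sv, n_train = n, iterations = sol$iter),
            class = "weighted_svm")
}

#' Decision values of a weighted SVM
#'
#' `f(x) = sum_i a_i y_i K(x_i, x) + b`; the sign is the predicted class
#' (ties at exactly zero go to the decoy class).
#'
#' @param object A `weighted_svm` model.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric decision values.
#' @export
screen_score.weighted_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv_x)) {
    stopf("feature length %d does not match training length %d",
          ncol(newdata), ncol(object$sv_x), class = "pharmboost_shape_error")
  }
  K <- rbf_kernel_matrix(newdata, object$sv_x, object$sigma)
  drop(K %*% object$coef) + object$b
}

#' @export
predict.weighted_svm <- function(object, newdata, ...) {
  sign_to_class(screen_score(object, newdata))
}

# tie at score 0 -> decoy (-1)
sign_to_class <- function(score) {
  ifelse(score > 0, 1L, -1L)
}

#' Screening score generic
#'
#' Real-valued ranking margin of a fitted screening model on new samples;
#' larger means more active-like. `sign(screen_score(...))` is the predicted
#' class.
#'
#' @param object A fitted model.
#' @param newdata Feature matrix or fingerprint tibble.
#' @param ... Method-specific arguments.
#' @return Numeric vector of scores.
#' @export
screen_score <- function(object, newdata, ...) UseMethod("screen_score")
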