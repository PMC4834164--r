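# Baseline screening models: plain RBF C-SVC (libsvm via e1071) and Random
# Forest (randomForest). Both expose the same screen_score()/predict()
# contract as the boosted ensemble.

#' Train the plain RBF-SVM baseline
#'
#' C-support vector classification with an RBF kernel and cost 5, the
#' single-classifier baseline the boosted ensemble is compared against. The
#' kernel width defaults to the adaptive rule (pooled standard deviation of
#' the training matrix) so the comparison with the ensemble is matched; a
#' fixed width (e.g. 0.001) can be given instead.
#'
#' @param x Feature matrix or fingerprint tibble.
#' @param y Labels +1/-1.
#' @param cost Soft-margin cost C (default 5).
#' @param sigma RBF width; `NULL` (default) uses [compute_sigma()] on `x`.
#' @param cross Optional k for libsvm's k-fold cross-validation accuracy
#'   (0 = off); recorded in the model, not used for selection.
#' @return A `plain_svm` model.
#' @export
train_plain_svm <- function(x, y, cost = 5, sigma = NULL, cross = 0) {
  if (is.data.frame(x)) x <- fp_matrix(x)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2L) {
    stopf("training requires both classes", class = "pharmboost_training_error")
  }
  if (is.null(sigma)) sigma <- compute_sigma(x)
  assert_number(sigma, "sigma", lower = .Machine$double.xmin)
  fit <- e1071::svm(x, factor(y), scale = FALSE, kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = cost,
                    cross = cross, probability = FALSE)
  # e1071's decision value is positive for the first of its internal labels
  first <- fit$levels[fit$labels[1L]]
  structure(list(sv_x = fit$SV, coef = as.numeric(fit$coefs), b = -fit$rho,
                 sign_to_active = if (first == "1") 1 else -1,
                 sigma = sigma, cost = cost,
                 cross_accuracy = if (cross > 0) fit$tot.accuracy else NA_real_,
                 n_sv = fit$tot.nSV),
            class = "plain_svm")
}

#' @rdname screen_score
#' @export
screen_score.plain_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- fp_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv_x)) {
    stopf("feature length %d does not match training length %d",
          ncol(newdata), ncol(object$sv_x), class = "pharmboost_shape_error")
  }
  K <- rbf_kernel_matrix(newdata, object$sv_x, object$sigma)
  object$sign_to_active * (drop(K %*% object$coef) + object$b)
}

#' @export
predict.plain_svm <- function(object, newdata, ...) {
  sign_to_class(screen_score(object, newdata))
}

#' @export
print.plain_svm <- function(x, ...) {
  cat(sprintf("<plain_svm> RBF C-SVC: C = %g, sigma = %.4g, %d support vectors\n",
              x$cost, x$sigma, x$n_sv))
  invisible(x)
}

#' Train the Random Forest baseline
#'
#' Defaults follow the reference configuration: 1000 trees, node size 5, 50
#' descriptors tried at each split. The screening score is the fraction of
#' trees voting for the active class.
#'
#' @param x Feature matrix or fingerprint tibble.
#' @param y Labels +1/-1.
#' @param n_trees,node_size,mtry Forest parameters (defaults 1000, 5, 50;
#'   `mtry` is capped at the number of features).
#' @param seed Integer seed (forest growth is randomized).
#' @return A `pharm_rf` model wrapping the randomForest fit.
#' @export
train_random_forest <- function(x, y, n_trees = 1000L, node_size = 5L,
                                mtry = 50L, seed = 1L) {
  if (is.data.frame(x)) x <- fp_matrix(x)
  x <- as.matrix(x); storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))  # RF needs syntactic names
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2L) {
    stopf("training requires both classes", class = "pharmboost_training_error")
  }
  fit <- with_seed(seed, randomForest::randomForest(
    x, factor(y, levels = c(-1, 1)), ntree = n_trees,
    nodesize = node_size, mtry = min(mtry, ncol(x))))
  structure(list(forest = fit, n_trees = n_trees, node_size = node_size,
                 mtry = min(mtry, ncol(x)), seed = seed,
                 n_features = ncol(x)),
            class = "pharm_rf")
}

#' @rdname screen_score
#' @export
screen_score.pharm_rf <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- fp_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stopf("feature length %d does not match training length %d",
          ncol(newdata), object$n_features, class = "pharmboost_shape_error")
  }
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  votes <- predict(object$forest, newdata, type = "vote")
  unname(votes[, "1"])
}

#' @export
predict.pharm_rf <- function(object, newdata, ...) {
  ifelse(screen_score(object, newdata) > 0.5, 1L, -1L)
}
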