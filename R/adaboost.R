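# AdaBoost over case-weighted RBF-SVM weak learners.
#
# Each boosting round trains a weighted SVM on the weight-trimmed sample
# set (kernel width = the trimmed set's pooled standard deviation in the
# adaptive mode), measures the weighted indicator error eps_t, stores the
# learner with vote a_t = 0.5 * ln((1 - eps_t) / eps_t), and reweights
# samples by exp(-+a_t) with renormalization. The strong classifier is
# H(x) = sign(sum_t a_t h_t(x)); the pre-sign margin is the screening score.

#' Boosting configuration
#'
#' @param n_iterations Boosting rounds T (default 5). In cascade mode, the
#'   number of layers.
#' @param max_learners_per_layer Cap on weak learners grown in one cascade
#'   layer (default 100).
#' @param weight_trim_rate Keep the largest-weight samples whose cumulative
#'   weight reaches this rate when training each weak learner (default 0.9).
#' @param max_false_alarm Cascade layer acceptance: maximum training
#'   false-positive rate (default 0.5).
#' @param min_hit_rate Cascade layer acceptance: minimum training
#'   true-positive rate (default 0.9).
#' @param cost Soft-margin cost C of the weak SVMs (default 5).
#' @param sigma_mode `"adaptive_std"` (width = pooled standard deviation of
#'   the current training set) or `"fixed"`.
#' @param fixed_sigma Width used when `sigma_mode = "fixed"` (default 0.001).
#' @param sigma_pool Passed to [compute_sigma()].
#' @param mode `"flat"` (default) or `"cascade"`.
#' @param per_feature If `TRUE`, each round trains one single-feature SVM per
#'   fingerprint column and keeps the lowest-weighted-error one.
#' @param epsilon_min Cap for zero training error when computing a_t.
#' @param seed Integer seed recorded with the model.
#' @return A list of class `boost_config`.
#' @export
boost_config <- function(n_iterations = 5L, max_learners_per_layer = 100L,
                         weight_trim_rate = 0.9, max_false_alarm = 0.5,
                         min_hit_rate = 0.9, cost = 5,
                         sigma_mode = c("adaptive_std", "fixed"),
                         fixed_sigma = 0.001,
                         sigma_pool = c("pooled", "per_feature_mean"),
                         mode = c("flat", "cascade"),
                         per_feature = FALSE, epsilon_min = 1e-10,
                         seed = 1L) {
  assert_number(n_iterations, "n_iterations", lower = 1)
  assert_number(weight_trim_rate, "weight_trim_rate", lower = 1e-12, upper = 1)
  assert_number(max_false_alarm, "max_false_alarm", lower = 1e-12, upper = 1)
  assert_number(min_hit_rate, "min_hit_rate", lower = 1e-12, upper = 1)
  assert_number(cost, "cost", lower = .Machine$double.xmin)
  assert_number(fixed_sigma, "fixed_sigma", lower = .Machine$double.xmin)
  structure(list(n_iterations = as.integer(n_iterations),
                 max_learners_per_layer = as.integer(max_learners_per_layer),
                 weight_trim_rate = weight_trim_rate,
                 max_false_alarm = max_false_alarm,
                 min_hit_rate = min_hit_rate, cost = cost,
                 sigma_mode = match.arg(sigma_mode),
                 fixed_sigma = fixed_sigma,
                 sigma_pool = match.arg(sigma_pool),
                 mode = match.arg(mode),
                 per_feature = isTRUE(per_feature),
                 epsilon_min = epsilon_min,
                 seed = as.integer(seed)),
            class = "boost_config")
}

#' Weighted classification error
#'
#' `eps = sum_i D_i * 1[pred_i != y_i]` for normalized weights `D`.
#'
#' @param predictions,labels Vectors of +1/-1.
#' @param weights Normalized sample weights.
#' @return Error in `[0, 1]`.
#' @export
weighted_error <- function(predictions, labels, weights) {
  stopifnot(length(predictions) == length(labels),
            length(weights) == length(labels))
  sum(weights[predictions != labels])
}

#' Weak-learner vote from its weighted error
#'
#' `a_t = 0.5 * ln((1 - eps) / eps)`. Zero error is capped at
#' `epsilon_min`; `eps = 0.5` gives a zero vote; `eps > 0.5` rejects the
#' learner with an error.
#'
#' @param epsilon Weighted error of the learner.
#' @param epsilon_min Cap applied when `epsilon` is 0.
#' @return The vote a_t >= 0.
#' @export
learner_weight <- function(epsilon, epsilon_min = 1e-10) {
  assert_number(epsilon, "epsilon", lower = 0, upper = 1)
  if (epsilon > 0.5) {
    stopf("learner rejected: weighted error %.4f >= 0.5", epsilon,
          class = "pharmboost_training_error")
  }
  epsilon <- max(epsilon, epsilon_min)
  0.5 * log((1 - epsilon) / epsilon)
}

#' AdaBoost weight update
#'
#' Correctly classified samples are downweighted by `exp(-a_t)`, wrongly
#' classified ones upweighted by `exp(+a_t)`; the vector is renormalized to
#' sum to one.
#'
#' @param weights Current normalized weights.
#' @param predictions,labels Vectors of +1/-1.
#' @param alpha The round's vote a_t.
#' @return Updated normalized weight vector.
#' @export
update_weights <- function(weights, predictions, labels, alpha) {
  w <- weights * exp(ifelse(predictions == labels, -alpha, alpha))
  w / sum(w)
}

#' Weight trimming mask
#'
#' Keeps the largest-weight samples whose cumulative weight reaches
#' `trim_rate`; the remainder are excluded from the next weak learner's
#' training set (their weights are retained for the updates). Ties keep
#' input order.
#'
#' @param weights Normalized sample weights.
#' @param trim_rate Cumulative-weight threshold in `(0, 1]`.
#' @return Logical mask over the samples (TRUE = train on it).
#' @export
trim_weights <- function(weights, trim_rate) {
  assert_number(trim_rate, "trim_rate", lower = 1e-12, upper = 1)
  ord <- order(weights, decreasing = TRUE)
  csum <- cumsum(weights[ord]) / sum(weights)
  k <- which(csum >= trim_rate - 1e-15)[1L]
  if (is.na(k)) k <- length(weights)
  mask <- logical(length(weights))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Train the AdaBoost-SVM ensemble
#'
#' Flat mode (default): `n_iterations` rounds of weight-trimmed, case-cost
#' weighted RBF-SVM weak learners with the standard AdaBoost reweighting;
#' boosting stops early on a perfect round (eps = 0) or when a round's
#' weighted error reaches 0.5. Cascade mode: up to `n_iterations` rejection
#' layers, each grown until its training hit rate and false-alarm rate meet
#' the configured targets.
#'
#' @param x Feature matrix or fingerprint tibble (rows = samples).
#' @param y Labels, +1 (active pose) / -1 (decoy pose).
#' @param config A [boost_config()].
#' @return An `adaboost_svm` model.
#' @export
train_adaboost <- function(x, y, config = boost_config()) {
  if (is.data.frame(x)) x <- fp_matrix(x)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2L) {
    stopf("training requires both classes", class = "pharmboost_training_error")
  }
  if (config$mode == "cascade") {
    return(train_adaboost_cascade(x, y, config))
  }
  fit <- boost_rounds(x, y, weights = rep(1 / nrow(x), nrow(x)),
                      config = config, max_rounds = config$n_iterations)
  if (!length(fit$learners)) {
    stopf("training failure: first weak learner had weighted error >= 0.5",
          class = "pharmboost_training_error")
  }
  finalize_adaboost(x, y, fit$learners, config, mode = "flat")
}

# Core boosting loop; returns learners (with sv indices into `x`) and the
# final weight vector. Used by both flat and cascade modes.
boost_rounds <- function(x, y, weights, config, max_rounds) {
  n <- nrow(x)
  D <- weights / sum(weights)
  learners <- list()
  for (t in seq_len(max_rounds)) {
    mask <- trim_weights(D, config$weight_trim_rate)
    if (length(unique(y[mask])) < 2L) break
    sigma <- if (config$sigma_mode == "adaptive_std") {
      compute_sigma(x[mask, , drop = FALSE], pool = config$sigma_pool)
    } else {
      config$fixed_sigma
    }
    wsvm <- fit_round_svm(x, y, mask, D, sigma, config)
    pred <- sign_to_class(screen_score(wsvm$model, x))
    eps <- weighted_error(pred, y, D)
    if (eps >= 0.5) {
      if (!length(learners)) {
        stopf("training failure: first weak learner had weighted error %.3f >= 0.5",
              eps, class = "pharmboost_training_error")
      }
      break
    }
    a <- learner_weight(eps, config$epsilon_min)
    learners[[length(learners) + 1L]] <- list(
      model = wsvm$model, alpha = a, epsilon = eps, sigma = sigma,
      iteration = t, n_train = sum(mask), feature = wsvm$feature)
    if (eps <= 0) break
    D <- update_weights(D, pred, y, a)
    stopifnot(abs(sum(D) - 1) < 1e-8)
  }
  list(learners = learners, weights = D)
}

# One round's weak learner: a full-feature weighted SVM, or (per-feature
# mode) the best single-feature weighted SVM.
fit_round_svm <- function(x, y, mask, D, sigma, config) {
  n <- nrow(x)
  if (!config$per_feature) {
    m <- train_weighted_svm(x[mask, , drop = FALSE], y[mask],
                            weights = D[mask], sigma = sigma,
                            cost = config$cost, n_total = n)
    m$feature_subset <- NULL
    return(list(model = m, feature = NA_integer_))
  }
  best <- NULL; best_eps <- Inf; best_f <- NA_integer_
  for (f in seq_len(ncol(x))) {
    xf <- x[, f, drop = FALSE]
    if (length(unique(xf[mask, 1L])) < 2L) next
    m <- tryCatch(
      train_weighted_svm(xf[mask, , drop = FALSE], y[mask], weights = D[mask],
                         sigma = sigma, cost = config$cost, n_total = n),
      error = function(e) NULL)
    if (is.null(m)) next
    eps <- weighted_error(sign_to_class(screen_score(m, xf)), y, D)
    if (eps < best_eps) { best <- m; best_eps <- eps; best_f <- f }
  }
  if (is.null(best)) {
    stopf("per-feature mode: no trainable feature found",
          class = "pharmboost_training_error")
  }
  list(model = best, feature = best_f)
}

# Package learners into the model object; store the support-vector rows once
# so scoring can share one distance computation across learners.
finalize_adaboost <- function(x, y, learners, config, mode, layers = NULL) {
  model <- structure(list(learners = learners, config = config, mode = mode,
                          layers = layers, n_features = ncol(x),
                          feature_names = colnames(x)),
                     class = "adaboost_svm")
  margin <- screen_score(model, x)
  pred <- sign_to_class(margin)
  model$train_error <- mean(pred != y)
  eps <- vapply(learners, `[[`, double(1), "epsilon")
  model$error_bound <- prod(2 * sqrt(pmax(eps, config$epsilon_min) *
                                       (1 - pmax(eps, config$epsilon_min))))
  model
}

#' Ensemble margin of the AdaBoost-SVM
#'
#' `margin(x) = sum_t a_t h_t(x)` with `h_t(x)` in `{+1, -1}`; screening
#' ranks by the margin, classification takes its sign (zero goes to decoy).
#'
#' @param object An `adaboost_svm` model.
#' @param newdata Feature matrix or fingerprint tibble.
#' @param ... Unused.
#' @return Numeric margins.
#' @export
screen_score.adaboost_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- fp_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stopf("feature length %d does not match training length %d",
          ncol(newdata), object$n_features, class = "pharmboost_shape_error")
  }
  margin <- numeric(nrow(newdata))
  for (lr in object$learners) {
    xd <- if (!is.na(lr$feature)) newdata[, lr$feature, drop = FALSE] else newdata
    h <- sign_to_class(screen_score(lr$model, xd))
    margin <- margin + lr$alpha * h
  }
  margin
}

#' @export
predict.adaboost_svm <- function(object, newdata, ...) {
  sign_to_class(screen_score(object, newdata))
}

#' @export
print.adaboost_svm <- function(x, ...) {
  cat(sprintf("<adaboost_svm> %s mode, %d weak learner(s), train error %.4f (bound %.4f)\n",
              x$mode, length(x$learners), x$train_error, x$error_bound))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-round summary of a boosted ensemble
#'
#' @param x An `adaboost_svm` model.
#' @param ... Unused.
#' @return A tibble with one row per weak learner: `iteration`, `epsilon`,
#'   `alpha`, `sigma`, `n_train`, `n_sv`.
#' @export
tidy.adaboost_svm <- function(x, ...) {
  purrr::map_dfr(x$learners, function(lr) {
    tibble(iteration = lr$iteration, epsilon = lr$epsilon, alpha = lr$alpha,
           sigma = lr$sigma, n_train = lr$n_train,
           n_sv = nrow(lr$model$sv_x))
  })
}

#' One-row model summary
#'
#' @param x An `adaboost_svm` model.
#' @param ... Unused.
#' @return A tibble with `n_learners`, `train_error`, `error_bound` (the
#'   AdaBoost bound `prod_t 2 sqrt(eps_t (1 - eps_t))`), `mode`.
#' @export
glance.adaboost_svm <- function(x, ...) {
  tibble(n_learners = length(x$learners), train_error = x$train_error,
         error_bound = x$error_bound, mode = x$mode)
}

#' Line plot of per-round error and vote
#'
#' @param object An `adaboost_svm` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adaboost_svm <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("epsilon", "alpha"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "boosting round", y = NULL)
}

# ---- cascade mode -----------------------------------------------------------

# Classic rejection-cascade construction over boosted layers: each layer is a
# small AdaBoost ensemble grown learner by learner until its training hit
# rate reaches min_hit_rate with false-alarm rate at most max_false_alarm
# (the layer threshold is lowered to the highest value that satisfies the
# hit-rate target). Samples rejected by a layer are dropped from later ones.
train_adaboost_cascade <- function(x, y, config) {
  active <- rep(TRUE, nrow(x))
  layers <- list()
  all_learners <- list()
  for (layer in seq_len(config$n_iterations)) {
    idx <- which(active)
    if (length(unique(y[idx])) < 2L) break
    xs <- x[idx, , drop = FALSE]; ys <- y[idx]
    D <- rep(1 / length(idx), length(idx))
    learners <- list()
    thr <- 0
    repeat {
      fit <- boost_rounds(xs, ys, D, config, max_rounds = 1L)
      if (!length(fit$learners)) break
      learners <- c(learners, fit$learners)
      D <- fit$weights
      margin <- cascade_layer_margin(learners, xs)
      pos <- margin[ys == 1L]
      # highest threshold keeping min_hit_rate of the positives
      thr <- stats::quantile(pos, probs = 1 - config$min_hit_rate,
                             names = FALSE, type = 1)
      hit <- mean(pos >= thr)
      fa <- mean(margin[ys == -1L] >= thr)
      done <- hit >= config$min_hit_rate && fa <= config$max_false_alarm
      if (done || length(learners) >= config$max_learners_per_layer ||
          fit$learners[[length(fit$learners)]]$epsilon <= 0) {
        break
      }
    }
    if (!length(learners)) break
    layers[[length(layers) + 1L]] <- list(learner_idx =
      length(all_learners) + seq_along(learners), threshold = thr)
    all_learners <- c(all_learners, learners)
    margin_all <- cascade_layer_margin(learners, x)
    active <- active & (margin_all >= thr)
    if (!any(active & y == -1L)) break
  }
  if (!length(all_learners)) {
    stopf("training failure: cascade produced no learners",
          class = "pharmboost_training_error")
  }
  model <- finalize_adaboost(x, y, all_learners, config, mode = "cascade",
                             layers = layers)
  model
}

cascade_layer_margin <- function(learners, x) {
  margin <- numeric(nrow(x))
  for (lr in learners) {
    xd <- if (!is.na(lr$feature)) x[, lr$feature, drop = FALSE] else x
    margin <- margin + lr$alpha * sign_to_class(screen_score(lr$model, xd))
  }
  margin
}

#' AdaBoost training-error bound
#'
#' The classical bound `prod_t 2 sqrt(eps_t (1 - eps_t))` on the training
#' error of the voted ensemble.
#'
#' @param model An `adaboost_svm` model.
#' @return The bound (a number in `[0, 1]`).
#' @export
boosting_error_bound <- function(model) {
  model$error_bound
}
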