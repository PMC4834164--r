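test_that("RBF kernel and adaptive width behave per their closed forms", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 0.5), 1.0)
  expect_equal(rbf_kernel(0, sqrt(2) * 0.7, 0.7), exp(-1))
  expect_error(rbf_kernel(x, x, 0), class = "pharmboost_argument_error")
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1),
               class = "pharmboost_shape_error")

  m <- matrix(c(0, 2, 0, 2), nrow = 2)   # entries {0, 2} equally frequent
  expect_equal(compute_sigma(m), 1.0)
  expect_equal(compute_sigma(3 * m), 3.0)          # homogeneity
  expect_warning(s0 <- compute_sigma(matrix(0, 4, 4)), "degenerate")
  expect_equal(s0, 1e-12)
})

test_that("the weighted SVM respects per-sample costs", {
  # separable two-point problem
  m <- train_weighted_svm(matrix(c(0, 5), ncol = 1), c(-1L, 1L),
                          sigma = 1, cost = 5)
  expect_equal(predict(m, matrix(c(0, 5), ncol = 1)), c(-1L, 1L))

  # XOR needs the kernel: perfectly fit with a narrow width
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  xor_y <- c(-1L, 1L, 1L, -1L)
  mx <- train_weighted_svm(xor_x, xor_y, sigma = 0.3, cost = 10)
  expect_equal(predict(mx, xor_x), xor_y)

  # upweighting the misclassified middle point flips it on retrain
  x3 <- matrix(c(0, 1, 1.2), ncol = 1); y3 <- c(1L, -1L, 1L)
  mu <- train_weighted_svm(x3, y3, weights = rep(1 / 3, 3), sigma = 0.5, cost = 1)
  expect_equal(predict(mu, x3)[2], 1L)  # middle point lost under uniform weights
  mw <- train_weighted_svm(x3, y3, weights = c(0.05, 0.9, 0.05),
                           sigma = 0.5, cost = 1)
  expect_equal(predict(mw, x3)[2], -1L)

  expect_error(train_weighted_svm(matrix(1:4, 2), c(1L, 1L)),
               class = "pharmboost_training_error")
})

test_that("uniform-weight SMO agrees with libsvm decision values", {
  set.seed(42)
  x <- rbind(matrix(rnorm(60, 1), 30), matrix(rnorm(60, -1), 30))
  y <- rep(c(1L, -1L), each = 30)
  ours <- train_weighted_svm(x, y, sigma = 1, cost = 5)
  f_ours <- screen_score(ours, x)
  ref <- e1071::svm(x, factor(y), scale = FALSE, kernel = "radial",
                    gamma = 1 / 2, cost = 5)
  f_ref <- attr(predict(ref, x, decision.values = TRUE), "decision.values")[, 1]
  if (ref$levels[ref$labels[1]] != "1") f_ref <- -f_ref
  expect_lt(max(abs(f_ours - f_ref)), 5e-3)
  expect_equal(sign(f_ours), unname(sign(f_ref)))
})

test_that("boosting algebra follows the weighted-vote update rules", {
  expect_equal(weighted_error(c(1, 1, -1, -1), c(1, 1, -1, -1), rep(0.25, 4)), 0)
  expect_equal(weighted_error(c(-1, -1, 1, 1), c(1, 1, -1, -1), rep(0.25, 4)), 1)
  expect_equal(weighted_error(c(1, 1, 1, -1), c(1, 1, -1, -1), rep(0.25, 4)), 0.25)

  expect_equal(learner_weight(0.5), 0)
  expect_equal(learner_weight(0.25), 0.5 * log(3))
  expect_gt(learner_weight(0.1), learner_weight(0.2))
  expect_equal(learner_weight(0), 0.5 * log((1 - 1e-10) / 1e-10))
  expect_error(learner_weight(0.6), class = "pharmboost_training_error")

  # all-correct round leaves normalized weights unchanged
  w <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(update_weights(w, c(1, 1, -1, -1), c(1, 1, -1, -1), 1), w)

  # uniform weights, one error, a = 0.5 ln 3: error weight becomes 1/2
  a <- 0.5 * log(3)
  up <- update_weights(rep(0.25, 4), c(-1, 1, 1, -1), c(1, 1, 1, -1), a)
  expect_equal(up, c(0.5, 1 / 6, 1 / 6, 1 / 6))
  expect_equal(sum(up), 1)
})

test_that("weight trimming keeps the top cumulative-weight samples", {
  expect_equal(trim_weights(c(0.1, 0.2, 0.3, 0.4), 1.0), rep(TRUE, 4))
  expect_equal(trim_weights(c(0.5, 0.3, 0.15, 0.05), 0.9),
               c(TRUE, TRUE, TRUE, FALSE))
  n <- 37
  expect_equal(sum(trim_weights(rep(1 / n, n), 0.9)), ceiling(0.9 * n))
})

test_that("the boosted ensemble trains, stops early, and is reproducible", {
  toy <- toy_separable()
  m <- train_adaboost(toy$x, toy$y, boost_config(seed = 1))
  expect_equal(length(m$learners), 1L)   # eps = 0 exits the loop
  expect_equal(m$train_error, 0)
  expect_equal(predict(m, toy$x), toy$y)

  ds <- gen_fingerprint_samples(small_synth(seed = 2))
  x <- fp_matrix(ds$train); y <- ds$train$label
  m1 <- train_adaboost(x, y, boost_config(seed = 7))
  m2 <- train_adaboost(x, y, boost_config(seed = 7))
  expect_equal(length(m1$learners), length(m2$learners))
  expect_equal(tidy(m1)$alpha, tidy(m2)$alpha)

  td <- tidy(m1)
  expect_true(all(td$epsilon >= 0 & td$epsilon < 0.5))
  keep <- td$epsilon > 0
  expect_equal(td$alpha[keep],
               0.5 * log((1 - td$epsilon[keep]) / td$epsilon[keep]))

  # margins equal the per-learner weighted vote recomputed by hand
  probe <- fp_matrix(ds$test)[1:5, , drop = FALSE]
  hand <- rowSums(sapply(m1$learners, function(lr) {
    lr$alpha * ifelse(screen_score(lr$model, probe) > 0, 1, -1)
  }))
  expect_equal(screen_score(m1, probe), hand, tolerance = 1e-12)

  # training error of the vote respects the AdaBoost product bound
  expect_lte(m1$train_error, boosting_error_bound(m1) + 1e-10)

  expect_error(train_adaboost(x[y == -1, ], y[y == -1]),
               class = "pharmboost_training_error")
})

test_that("ensemble training error is non-increasing over boosting rounds", {
  ds <- gen_fingerprint_samples(small_synth(seed = 5))
  x <- fp_matrix(ds$train); y <- ds$train$label
  m <- train_adaboost(x, y, boost_config(seed = 5))
  h <- sapply(m$learners, function(lr) {
    ifelse(screen_score(lr$model, x) > 0, 1, -1)
  })
  a <- tidy(m)$alpha
  errs <- sapply(seq_along(a), function(t) {
    margin <- h[, seq_len(t), drop = FALSE] %*% a[seq_len(t)]
    mean(ifelse(margin > 0, 1L, -1L) != y)
  })
  expect_lte(errs[length(errs)], errs[1] + 1e-12)
})

test_that("cascade mode produces a layered model with the same score contract", {
  ds <- gen_fingerprint_samples(small_synth(seed = 3))
  x <- fp_matrix(ds$train); y <- ds$train$label
  m <- train_adaboost(x, y, boost_config(mode = "cascade", seed = 3))
  expect_s3_class(m, "adaboost_svm")
  expect_gt(length(m$learners), 0L)
  expect_true(length(m$layers) >= 1L)
  s <- screen_score(m, fp_matrix(ds$test)[1:10, ])
  expect_length(s, 10L)
})

test_that("baselines expose the shared score contract and sane defaults", {
  toy <- toy_separable()
  svm <- train_plain_svm(toy$x, toy$y)
  rf <- train_random_forest(toy$x, toy$y, n_trees = 200, seed = 1)
  expect_equal(predict(svm, toy$x), toy$y)
  expect_equal(predict(rf, toy$x), toy$y)

  ds <- gen_fingerprint_samples(small_synth(seed = 4))
  x <- fp_matrix(ds$train); y <- ds$train$label
  xt <- fp_matrix(ds$test); yt <- ds$test$label

  # forest scores are vote fractions; two seeds agree closely on AUC
  r1 <- train_random_forest(x, y, seed = 1)
  r2 <- train_random_forest(x, y, seed = 2)
  expect_equal(r1$n_trees, 1000L)
  expect_equal(r1$forest$forest$nodesize %||% 5L, 5L)
  s1 <- screen_score(r1, xt)
  expect_true(all(s1 >= 0 & s1 <= 1))
  auc1 <- screen_auc(ranked_screen(s1, yt))
  auc2 <- screen_auc(ranked_screen(screen_score(r2, xt), yt))
  expect_lt(abs(auc1 - auc2), 0.05)

  # fixed seed reproduces the forest
  r1b <- train_random_forest(x, y, seed = 1)
  expect_equal(screen_score(r1b, xt[1:20, ]), screen_score(r1, xt[1:20, ]))

  # fixed-width mode is available for the plain baseline
  svm_fixed <- train_plain_svm(x, y, sigma = 0.001)
  expect_equal(svm_fixed$sigma, 0.001)
})

test_that("models serialize to self-describing files and score identically", {
  ds <- gen_fingerprint_samples(small_synth(seed = 6))
  x <- fp_matrix(ds$train); y <- ds$train$label
  probe <- fp_matrix(ds$test)[1:8, ]

  ada <- train_adaboost(x, y, boost_config(seed = 6))
  path <- write_model(ada, withr::local_tempfile(fileext = ".json"))
  ada2 <- read_model(path)
  expect_equal(screen_score(ada2, probe), screen_score(ada, probe),
               tolerance = 1e-10)
  expect_equal(tidy(ada2)$epsilon, tidy(ada)$epsilon, tolerance = 1e-12)

  svm <- train_plain_svm(x, y)
  spath <- write_model(svm, withr::local_tempfile(fileext = ".json"))
  expect_equal(screen_score(read_model(spath), probe),
               screen_score(svm, probe), tolerance = 1e-10)

  rf <- train_random_forest(x, y, n_trees = 100, seed = 1)
  rpath <- write_model(rf, withr::local_tempfile(fileext = ".rds"))
  expect_equal(screen_score(read_model(rpath), probe),
               screen_score(rf, probe))
})
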