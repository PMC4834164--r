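test_that("enrichment factor follows the top-fraction definition", {
  # 10 samples, both actives ranked on top, 10% sampling: N_s = 1, EF = 5
  scr <- ranked_screen(score = 10:1, label = c(1, 1, rep(-1, 8)))
  expect_equal(enrichment_factor(scr, 0.1), 5)

  # all actives ranked last -> EF 0
  worst <- ranked_screen(score = 10:1, label = c(rep(-1, 8), 1, 1))
  expect_equal(enrichment_factor(worst, 0.1), 0)

  # EF bounds attained by perfect ranking: min(N_t/N_s, N_t/Hit_t)
  expect_equal(enrichment_factor(scr, 0.2), min(10 / 2, 10 / 2))

  expect_error(enrichment_factor(ranked_screen(1:3, rep(-1, 3)), 0.5),
               class = "pharmboost_degenerate_error")
  expect_error(enrichment_factor(scr, 1.5), class = "pharmboost_argument_error")

  # ceiling rounding guarantees at least one sampled compound; a pure-active
  # top-1 saturates at N_t / Hit_t
  expect_equal(enrichment_factor(scr, 0.01), 5)
})

test_that("ROC handles perfect separation, full ties, and matches brute force", {
  perfect <- ranked_screen(c(5, 4, 1, 0), c(1, 1, -1, -1))
  roc <- roc_curve(perfect)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(screen_auc(roc), 1.0)

  tied <- ranked_screen(rep(2, 6), c(1, 1, -1, -1, -1, 1))
  roc_t <- roc_curve(tied)
  expect_equal(nrow(roc_t), 2L)
  expect_equal(screen_auc(roc_t), 0.5)

  # 4-sample fixture vs explicit threshold sweep
  fix <- ranked_screen(c(0.9, 0.8, 0.7, 0.1), c(1, -1, 1, -1))
  roc_f <- roc_curve(fix)
  expect_equal(roc_f$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(roc_f$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(screen_auc(roc_f), 0.75)
  expect_equal(screen_auc(roc_f), mw_auc(fix$score, fix$label))

  expect_error(roc_curve(ranked_screen(1:3, rep(1, 3))),
               class = "pharmboost_degenerate_error")
})

test_that("AUC equals the pairwise statistic and respects its symmetries", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    score <- sample(round(runif(n, 0, 5), 1))  # coarse grid forces ties
    label <- ifelse(runif(n) < 0.4, 1L, -1L)
    if (length(unique(label)) < 2L) next
    scr <- ranked_screen(score, label)
    expect_equal(screen_auc(roc_curve(scr)), mw_auc(score, label),
                 tolerance = 1e-9)
    # monotone transform leaves AUC unchanged
    expect_equal(screen_auc(ranked_screen(exp(score), label)),
                 screen_auc(scr), tolerance = 1e-12)
  }

  # reversal duality without ties
  set.seed(5)
  sc <- rnorm(30); lb <- rep(c(1L, -1L), 15)
  expect_equal(screen_auc(ranked_screen(-sc, lb)),
               1 - screen_auc(ranked_screen(sc, lb)), tolerance = 1e-12)

  # independent reference implementation agrees
  skip_if_not_installed("pROC")
  a <- suppressMessages(pROC::auc(pROC::roc(lb, sc, direction = "<",
                                            quiet = TRUE)))
  expect_equal(screen_auc(ranked_screen(sc, lb)), as.numeric(a),
               tolerance = 1e-9)
})

test_that("trial aggregation reports mean and sd per metric", {
  r1 <- tibble::tibble(metric = c("ef_0.1", "auc"), value = c(4, 0.8))
  r2 <- tibble::tibble(metric = c("ef_0.1", "auc"), value = c(6, 0.9))
  agg <- aggregate_trials(list(r1, r2))
  expect_equal(agg$mean[agg$metric == "ef_0.1"], 5)
  expect_equal(agg$sd[agg$metric == "ef_0.1"], sqrt(2))
  expect_equal(agg$n_trials, c(2L, 2L))

  one <- aggregate_trials(list(r1))
  expect_equal(one$mean, r1$value)
  expect_equal(one$sd, c(0, 0))

  swapped <- aggregate_trials(list(r2, r1))
  expect_equal(dplyr::arrange(agg, metric), dplyr::arrange(swapped, metric))

  expect_error(aggregate_trials(list()))
})

test_that("pose-to-compound aggregation takes the best pose", {
  scr <- ranked_screen(score = c(3, 5, 2, 1, 9, 4),
                       label = c(1, 1, 1, -1, -1, -1),
                       compound = c("a", "a", "a", "b", "b", "b"))
  cmp <- pose_to_compound(scr)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$score[cmp$id == "a"], 5)
  expect_equal(cmp$score[cmp$id == "b"], 9)

  # order-preserving on a separable fixture
  sep <- ranked_screen(score = c(9, 8, 2, 1), label = c(1, 1, -1, -1),
                       compound = c("a", "a", "b", "b"))
  expect_equal(screen_auc(roc_curve(pose_to_compound(sep))), 1)

  bad <- ranked_screen(score = 1:2, label = c(1, -1), compound = c("a", "a"))
  expect_error(pose_to_compound(bad), "conflicting")
})

test_that("screens round-trip through the TSV format", {
  scr <- ranked_screen(score = c(0.4, 0.1, 0.9), label = c(1, -1, -1),
                       id = c("p1", "p2", "p3"), compound = c("x", "y", "y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen(scr, path)
  back <- read_screen(path)
  expect_equal(as.data.frame(back), as.data.frame(scr))
  expect_equal(screen_metrics(back)$value, screen_metrics(scr)$value)
})
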