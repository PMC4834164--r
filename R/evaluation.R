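# Screening-efficiency metrics: enrichment factor at a sampling fraction,
# ROC curve, AUC, multi-trial aggregation, and pose-to-compound collapsing.
#
# A "ranked screen" is a tibble with columns `id`, `score`, `label` (+1
# active / -1 decoy) and optionally `compound`.

#' Assemble a ranked screen
#'
#' @param score Numeric screening scores (higher = more active-like).
#' @param label Labels, +1 (active) / -1 (decoy).
#' @param id Sample identifiers (default `s1, s2, ...`).
#' @param compound Optional compound id per sample (poses of one compound
#'   share it).
#' @return A tibble of class `ranked_screen`.
#' @export
ranked_screen <- function(score, label, id = NULL, compound = NULL) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  if (!all(label %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (any(!is.finite(score))) stopf("scores must be finite")
  out <- tibble(id = id %||% paste0("s", seq_along(score)),
                score = as.numeric(score), label = label)
  if (!is.null(compound)) out$compound <- as.character(compound)
  class(out) <- c("ranked_screen", class(out))
  out
}

check_two_classes <- function(screen) {
  if (!any(screen$label == 1L) || !any(screen$label == -1L)) {
    stopf("EF/ROC need at least one active and one decoy",
          class = "pharmboost_degenerate_error")
  }
}

#' Enrichment factor at a sampling fraction
#'
#' `EF = (Hits_s / N_s) / (Hit_t / N_t)`: the active hit-rate among the top
#' `N_s = ceiling(fraction * N_t)` ranked samples relative to the overall
#' hit-rate. Ranking sorts by score descending with a stable tie-break on
#' input order.
#'
#' @param screen A [ranked_screen()] (any tibble with `score`, `label`).
#' @param fraction Sampling fraction s in `(0, 1]` (default 0.1, the 10% EF).
#' @return The enrichment factor (>= 0).
#' @export
enrichment_factor <- function(screen, fraction = 0.1) {
  assert_number(fraction, "fraction", lower = 1e-12, upper = 1)
  check_two_classes(screen)
  n_t <- nrow(screen)
  n_s <- ceiling(fraction * n_t)
  ord <- order(-screen$score)  # radix sort: stable on ties
  top <- screen$label[ord][seq_len(n_s)]
  hits_s <- sum(top == 1L)
  hit_t <- sum(screen$label == 1L)
  (hits_s / n_s) / (hit_t / n_t)
}

#' ROC curve of a ranked screen
#'
#' One point per distinct score threshold (descending); samples with equal
#' scores move together, producing diagonal segments; the curve starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param screen A [ranked_screen()].
#' @return A tibble with columns `threshold`, `fpr`, `tpr` of class
#'   `screen_roc`.
#' @export
roc_curve <- function(screen) {
  check_two_classes(screen)
  P <- sum(screen$label == 1L)
  N <- sum(screen$label == -1L)
  by_thr <- screen |>
    dplyr::summarise(tp = sum(.data$label == 1L), fp = sum(.data$label == -1L),
                     .by = "score") |>
    dplyr::arrange(dplyr::desc(.data$score))
  out <- tibble(threshold = c(Inf, by_thr$score),
                fpr = c(0, cumsum(by_thr$fp) / N),
                tpr = c(0, cumsum(by_thr$tp) / P))
  class(out) <- c("screen_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of TPR over FPR. Equivalent (property-tested) to the
#' pairwise Mann-Whitney statistic `P(score_active > score_decoy) +
#' 0.5 P(tie)`.
#'
#' @param roc A `screen_roc` tibble from [roc_curve()], or a ranked screen
#'   (in which case the curve is computed first).
#' @return AUC in `[0, 1]`.
#' @export
screen_auc <- function(roc) {
  if (!inherits(roc, "screen_roc")) roc <- roc_curve(roc)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Metric report for a ranked screen
#'
#' @param screen A [ranked_screen()].
#' @param fractions EF sampling fractions (default 0.1).
#' @return A tibble with columns `metric`, `value`; EF rows are named
#'   `ef_<fraction>`, plus an `auc` row.
#' @export
screen_metrics <- function(screen, fractions = 0.1) {
  efs <- vapply(fractions, function(s) enrichment_factor(screen, s), double(1))
  tibble(metric = c(sprintf("ef_%g", fractions), "auc"),
         value = c(efs, screen_auc(roc_curve(screen))))
}

#' Aggregate metric reports over trials
#'
#' Arithmetic mean and sample standard deviation per metric; a single trial
#' reports sd 0.
#'
#' @param reports A list of tibbles from [screen_metrics()] (identical
#'   metric keys), or one tibble with a `trial` column.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n_trials`.
#' @export
aggregate_trials <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (!length(reports)) stopf("no reports to aggregate")
  keys <- lapply(reports, function(r) r$metric)
  if (length(unique(lapply(keys, sort))) != 1L) {
    stopf("reports carry different metric keys")
  }
  dplyr::bind_rows(reports) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
      n_trials = dplyr::n(),
      .by = "metric")
}

#' Collapse docking poses to compounds
#'
#' One row per compound, scored by the maximum over its poses; the compound
#' keeps its (necessarily unique) label.
#'
#' @param screen A [ranked_screen()] with a `compound` column.
#' @param rule Aggregation rule; only `"max_score"` is provided.
#' @return A compound-level [ranked_screen()].
#' @export
pose_to_compound <- function(screen, rule = "max_score") {
  rule <- match.arg(rule, "max_score")
  if (is.null(screen[["compound"]])) {
    stopf("`screen` has no `compound` column")
  }
  agg <- screen |>
    dplyr::summarise(score = max(.data$score),
                     n_labels = dplyr::n_distinct(.data$label),
                     label = .data$label[1L], .by = "compound")
  if (any(agg$n_labels > 1L)) {
    stopf("compound(s) with conflicting pose labels: %s",
          paste(agg$compound[agg$n_labels > 1L], collapse = ", "))
  }
  ranked_screen(agg$score, agg$label, id = agg$compound,
                compound = agg$compound)
}

#' ROC plot
#'
#' @param object A `screen_roc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", screen_auc(object)))
}

#' Write / read screening scores as TSV
#'
#' Columns `id`, `score`, `label` and optionally `compound`.
#'
#' @param screen A [ranked_screen()].
#' @param path File path.
#' @return The screen (reader) or `path` invisibly (writer).
#' @export
write_screen <- function(screen, path) {
  readr::write_tsv(as_tibble(screen), path)
  invisible(path)
}

#' @rdname write_screen
#' @export
read_screen <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ranked_screen(df$score, df$label, id = df$id, compound = df[["compound"]])
}
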