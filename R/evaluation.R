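#' Region identification metrics
#'
#' Precision, recall and F1 (as percentages) of a predicted binary region
#' against the reference, over the valid (non-padding) vertices. An
#' undefined precision (no positive predictions) or recall (no positive
#' truth) is reported as 0 and flagged.
#'
#' @param pred per-vertex 0/1 prediction.
#' @param truth per-vertex 0/1 reference.
#' @param mask optional logical vector of valid vertices.
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (percent), `precision_defined`, `recall_defined`.
#' @export
region_metrics <- function(pred, truth, mask = NULL) {
  assert_that(length(pred) == length(truth),
              "pred and truth must have equal length",
              "hinge3_dimension_error")
  if (!is.null(mask)) {
    pred <- pred[mask]; truth <- truth[mask]
  }
  p <- pred > 0; t <- truth > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  prec_def <- (tp + fp) > 0
  rec_def <- (tp + fn) > 0
  precision <- if (prec_def) 100 * tp / (tp + fp) else 0
  recall <- if (rec_def) 100 * tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, precision_defined = prec_def,
                 recall_defined = rec_def)
}

#' Centroid prediction error (PreE, mm)
#'
#' Matches centroids by nearest Euclidean distance and averages the matched
#' distances. The primary direction is truth-to-nearest-prediction, which
#' penalises missed hinges; `"pred_to_truth"` and the `"symmetric"` mean of
#' the two are available since excess predictions are otherwise free.
#'
#' @param pred predicted centroid coordinates: a `centroid_set` tibble or an
#'   n x 3 matrix.
#' @param truth reference centroid coordinates, m x 3 matrix (m >= 1).
#' @param direction matching rule; default `"truth_to_pred"`.
#' @return mean matched distance in mm; `Inf` if there are no predictions.
#' @export
centroid_pre <- function(pred, truth,
                         direction = c("truth_to_pred", "pred_to_truth",
                                       "symmetric")) {
  direction <- match.arg(direction)
  if (inherits(pred, "centroid_set") || is.data.frame(pred)) {
    pred <- as.matrix(pred[, c("x", "y", "z")])
  }
  pred <- matrix(as.numeric(pred), ncol = 3)
  truth <- matrix(as.numeric(truth), ncol = 3)
  assert_that(nrow(truth) >= 1, "truth centroid set must be nonempty")
  if (nrow(pred) == 0) return(Inf)
  one_way <- function(from, to) {
    mean(RANN::nn2(to, from, k = 1L)$nn.dists[, 1])
  }
  switch(direction,
         truth_to_pred = one_way(truth, pred),
         pred_to_truth = one_way(pred, truth),
         symmetric = (one_way(truth, pred) + one_way(pred, truth)) / 2)
}

#' Aggregate per-subject metrics into an evaluation report
#'
#' `macro` averages each per-subject metric (F1 is the mean of per-subject
#' F1 values); `micro` pools the confusion counts and recomputes. PreE is
#' averaged over hemispheres within subject (whole-brain PreE) and across
#' subjects (lh-PreE, rh-PreE, mean-PreE).
#'
#' @param per_subject tibble with one row per subject-hemisphere and columns
#'   `subject_id`, `hemisphere`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `pre` (PreE, mm; `NA`/`Inf` treated as missing for averaging).
#' @param aggregation `"macro"` (default) or `"micro"`.
#' @return an `eval_report`: list with `summary` (one-row tibble:
#'   `precision`, `recall`, `f1`, `lh_pre`, `rh_pre`, `mean_pre`,
#'   `n_subjects`, `aggregation`) and `per_subject`.
#' @export
aggregate_subjects <- function(per_subject,
                               aggregation = c("macro", "micro")) {
  aggregation <- match.arg(aggregation)
  assert_that(nrow(per_subject) >= 1, "need at least one subject record")
  ps <- per_subject
  finite_mean <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  if (aggregation == "macro") {
    precision <- mean(ps$precision); recall <- mean(ps$recall)
    f1 <- mean(ps$f1)
  } else {
    tp <- sum(ps$tp); fp <- sum(ps$fp); fn <- sum(ps$fn)
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  lh_pre <- finite_mean(ps$pre[ps$hemisphere == "lh"])
  rh_pre <- finite_mean(ps$pre[ps$hemisphere == "rh"])
  subj_pre <- dplyr::summarise(
    dplyr::group_by(ps, .data$subject_id),
    pre = finite_mean(.data$pre), .groups = "drop")
  mean_pre <- finite_mean(subj_pre$pre)
  out <- list(summary = tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    lh_pre = lh_pre, rh_pre = rh_pre, mean_pre = mean_pre,
    n_subjects = dplyr::n_distinct(ps$subject_id),
    aggregation = aggregation),
    per_subject = ps)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<eval_report> %d subject(s), %s aggregation\n  P %.2f%%  R %.2f%%  F1 %.2f%%  lh-PreE %.2f  rh-PreE %.2f  mean-PreE %.2f mm\n",
    s$n_subjects, s$aggregation, s$precision, s$recall, s$f1,
    s$lh_pre, s$rh_pre, s$mean_pre))
  invisible(x)
}

#' @rdname aggregate_subjects
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
glance.eval_report <- function(x, ...) x$summary

#' @rdname aggregate_subjects
#' @export
tidy.eval_report <- function(x, ...) x$per_subject

#' Correlation between identification accuracy and gender
#'
#' Pearson (point-biserial) correlation between a per-subject accuracy
#' metric and a binary gender label, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (computed via [stats::cor.test()]). No multiple-testing correction is
#' applied across feature combinations; when reporting several combinations
#' the p-values are raw, which the report flags.
#'
#' @param accuracy numeric per-subject accuracy values (e.g. per-subject F1
#'   of region identification).
#' @param gender 0/1 labels, both present; `n >= 3`.
#' @return one-row tibble: `r`, `p_value`, `n`, `multiple_testing`.
#' @export
gender_correlation <- function(accuracy, gender) {
  assert_that(length(accuracy) == length(gender),
              "accuracy and gender must have equal length",
              "hinge3_dimension_error")
  assert_that(length(accuracy) >= 3, "need n >= 3 subjects")
  assert_that(length(unique(gender)) == 2, "both genders must be present")
  assert_that(sd(accuracy) > 0, "accuracy must be non-constant")
  ct <- stats::cor.test(accuracy, as.numeric(gender), method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(accuracy), multiple_testing = "none (raw p)")
}
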