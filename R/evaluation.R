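#' Confusion counts for binary adherence predictions
#'
#' The positive class is the adherent day (label 1).
#'
#' @param labels Integer 0/1 vector of true adherence labels.
#' @param predictions Integer 0/1 vector of predicted labels, same length.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) == 0) abort("`labels` must be non-empty")
  if (length(labels) != length(predictions)) {
    abort(sprintf("length mismatch: %d labels vs %d predictions",
                  length(labels), length(predictions)))
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    abort("labels and predictions must be 0/1")
  }
  tibble(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0),
    tn = sum(labels == 0 & predictions == 0)
  )
}

# Rank (pairwise-comparison) formulation of the area under the ROC curve;
# ties between a positive and a negative score count one half.  NA when the
# labels are single-class (no ROC curve exists).
auc_rank <- function(labels, scores) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)                     # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Five-metric evaluation of one participant's test predictions
#'
#' Computes precision, recall, F1 (harmonic mean of the two), AUC and
#' accuracy, with the adherent day as the positive class.  A metric whose
#' denominator is empty (no predicted positives, no true positives, or
#' single-class labels for the AUC) is reported as `NA` rather than imputed;
#' [aggregate_metrics()] excludes such values from the macro means and
#' reports how many participants were excluded.
#'
#' @param counts A one-row tibble from [confusion_counts()].
#' @param scores Numeric vector of predicted adherence probabilities (used
#'   for the AUC), aligned with `labels`.
#' @param labels Integer 0/1 vector of true labels.
#' @return A one-row tibble with columns `precision`, `recall`, `f1`, `auc`,
#'   `accuracy`, `n_test`.
#' @export
#' @examples
#' cc <- tibble::tibble(tp = 3, fp = 1, fn = 1, tn = 5)
#' adherence_metrics(cc, scores = NULL, labels = NULL)
adherence_metrics <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  auc <- if (is.null(scores) || is.null(labels)) {
    NA_real_
  } else {
    if (length(scores) != length(labels)) {
      abort("`scores` and `labels` must be aligned")
    }
    auc_rank(labels, scores)
  }
  tibble(precision = precision, recall = recall, f1 = f1, auc = auc,
         accuracy = (tp + tn) / total, n_test = as.integer(total))
}

#' Evaluate a fitted model on a participant's test samples
#'
#' Convenience wrapper: predicts probabilities for the test samples,
#' thresholds them, and computes the five metrics.
#'
#' @param model An `adherence_model`.
#' @param test_samples Test tibble of a [supervised_split][make_supervised].
#' @param threshold Decision threshold for the hard calls.
#' @return A one-row metrics tibble (see [adherence_metrics()]).
#' @export
evaluate_model <- function(model, test_samples, threshold = 0.5) {
  scores <- predict(model, test_samples, type = "prob")
  predictions <- as.integer(scores >= threshold)
  labels <- as.integer(test_samples$label)
  adherence_metrics(confusion_counts(labels, predictions), scores, labels)
}

#' Macro-average per-participant metrics across a cohort
#'
#' Unweighted mean of each metric over the participants for which it is
#' defined, alongside the count of participants contributing to (and
#' excluded from) each mean.  Optionally also returns micro-averages
#' (pooling all test days before computing each metric is left to the
#' caller; here "micro" weights participants by their number of test days).
#'
#' @param per_participant A tibble with one row per participant containing
#'   at least the columns `precision`, `recall`, `f1`, `auc`, `accuracy`,
#'   `n_test`.
#' @param weighted If `TRUE`, weight participants by `n_test` instead of
#'   equally.
#' @return A tibble with one row per metric: `metric`, `mean`,
#'   `n_participants`, `n_excluded`.
#' @export
aggregate_metrics <- function(per_participant, weighted = FALSE) {
  if (nrow(per_participant) == 0) abort("no participant metrics to aggregate")
  metric_names <- c("precision", "recall", "f1", "auc", "accuracy")
  rows <- lapply(metric_names, function(mname) {
    vals <- per_participant[[mname]]
    ok <- !is.na(vals)
    wts <- if (weighted) per_participant$n_test[ok] else rep(1, sum(ok))
    tibble(
      metric = mname,
      mean = if (any(ok)) sum(vals[ok] * wts) / sum(wts) else NA_real_,
      n_participants = sum(ok),
      n_excluded = sum(!ok)
    )
  })
  bind_rows(rows)
}
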