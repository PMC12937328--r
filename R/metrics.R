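# Classification metrics: overall accuracy (OA), mean class accuracy (mAcc)
# and the confusion matrix they derive from.

#' Build a metrics report from a confusion matrix
#'
#' The confusion matrix has true classes on rows and predicted classes on
#' columns. OA is the trace over the total count; mAcc is the unweighted
#' mean of per-class accuracies (diagonal over row sums), which is robust to
#' class imbalance. Classes absent from the test set (zero row sum) have
#' undefined per-class accuracy and are excluded from the mAcc mean with a
#' warning.
#'
#' @param confusion square numeric matrix of counts.
#' @return list of class `metrics_report` with elements `oa`, `macc`,
#'   `per_class_acc` and `confusion`.
#' @export
metrics_report <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stopf("`confusion` must be a square matrix")
  if (any(confusion < 0)) stopf("confusion counts must be non-negative")
  totals <- rowSums(confusion)
  if (sum(totals) == 0) stopf("confusion matrix is empty")
  per_class <- ifelse(totals > 0, diag(confusion) / totals, NA_real_)
  if (anyNA(per_class))
    warnf("%d class(es) absent from the test set; excluded from mAcc",
          sum(is.na(per_class)))
  structure(list(oa = sum(diag(confusion)) / sum(confusion),
                 macc = mean(per_class, na.rm = TRUE),
                 per_class_acc = per_class,
                 confusion = confusion),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> OA = %.4f | mAcc = %.4f | %d classes\n",
              x$oa, x$macc, nrow(x$confusion)))
  invisible(x)
}

confusion_from_predictions <- function(truth, pred, num_classes) {
  cm <- matrix(0, num_classes, num_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
  cm
}

#' Evaluate a model on a labelled sample set
#'
#' Runs deterministic evaluation-mode forward passes in batches and tallies
#' the confusion matrix (true class on rows, predicted on columns).
#'
#' @param model a `dk_model`.
#' @param samples list of [pc_sample()] objects whose clouds already have
#'   the model's input point count (see [prepare_dataset()]).
#' @param batch_size evaluation batch size.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, samples, batch_size = 16) {
  if (!length(samples)) stopf("`samples` is empty")
  truth <- sample_labels(samples)
  pred <- integer(length(samples))
  starts <- seq(1L, length(samples), by = batch_size)
  for (s in starts) {
    ix <- s:min(s + batch_size - 1L, length(samples))
    batch <- lapply(samples[ix], `[[`, "cloud")
    pred[ix] <- predict(model, batch)
  }
  metrics_report(confusion_from_predictions(truth, pred, model$cfg$num_classes))
}
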