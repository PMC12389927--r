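# Evaluation metrics and the sensor-ablation harness.

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall and F1 from the four confusion
#' counts, with `"correct"` execution as the positive class. When a ratio
#' is undefined (empty denominator) it is reported as 0 by convention and
#' the result is flagged via the `degenerate` field.
#'
#' @param tp,fp,fn,tn Non-negative integer confusion counts (true/false
#'   positives/negatives).
#' @return An object of class `eval_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, the four counts, and `degenerate`.
#' @export
#' @examples
#' eval_metrics(tp = 45, fp = 5, fn = 3, tn = 47)
eval_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- TRUE; 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- TRUE; 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else {
      degenerate <- TRUE; 0
    }
  structure(list(accuracy = (tp + tn) / total, precision = precision,
                 recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn,
                 tn = tn, degenerate = degenerate),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> accuracy %.3f | precision %.3f | recall %.3f | f1 %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  cat("  TP ", x$tp, " FP ", x$fp, " FN ", x$fn, " TN ", x$tn,
      if (x$degenerate) "  (degenerate: undefined ratio reported as 0)",
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained classifier on labelled windows
#'
#' @param classifier A trained [fit_window_classifier()] model.
#' @param dataset A `window_dataset`; by default its `"test"` part is used.
#' @param part `"test"` (default), `"train"`, or `"all"`.
#' @return An [eval_metrics()] object.
#' @export
evaluate <- function(classifier, dataset, part = c("test", "train", "all")) {
  part <- match.arg(part)
  stopifnot(inherits(dataset, "window_dataset"))
  if (part != "all") dataset <- dataset_part(dataset, part)
  if (dim(dataset$x)[1L] == 0L)
    stop("evaluation set is empty", call. = FALSE)
  pred <- predict(classifier, dataset)
  truth <- dataset$y
  eval_metrics(tp = sum(pred == "correct" & truth == "correct"),
               fp = sum(pred == "correct" & truth == "incorrect"),
               fn = sum(pred == "incorrect" & truth == "correct"),
               tn = sum(pred == "incorrect" & truth == "incorrect"))
}

#' Sensor-ablation study
#'
#' Quantifies the contribution of each sensor group by retraining the window
#' classifier with channel groups removed -- `"full"` (all 8 channels),
#' `"no_IMU"` (flex sensors only) and `"no_flex"` (IMU only) -- under a
#' shared seed, and evaluating each model on the same held-out windows.
#'
#' @param dataset A [build_dataset()] result covering all 8 channels.
#' @param channel_groups Character vector of channel-group names.
#' @param seed Shared training seed.
#' @param architecture A [window_cnn()] descriptor used for every group.
#' @return A data frame of class `ablation_study` with one row per channel
#'   group: `group`, `n_channels`, `accuracy`, `precision`, `recall`, `f1`,
#'   and `delta_accuracy` relative to the full model.
#' @export
ablation_study <- function(dataset,
                           channel_groups = c("full", "no_IMU", "no_flex"),
                           seed = 1, architecture = window_cnn()) {
  stopifnot(inherits(dataset, "window_dataset"))
  if (!all(.rg_channels %in% dataset$channels))
    stop("dataset must cover all 8 sensor channels", call. = FALSE)
  rows <- lapply(channel_groups, function(g) {
    chans <- resolve_channels(g)     # errors on unknown group names
    clf <- fit_window_classifier(dataset, channels = g,
                                 architecture = architecture, seed = seed)
    m <- evaluate(clf, dataset, part = "test")
    data.frame(group = g, n_channels = length(chans),
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  out <- do.call(rbind, rows)
  ref <- if ("full" %in% out$group) out$accuracy[out$group == "full"][1L]
  else out$accuracy[1L]
  out$delta_accuracy <- out$accuracy - ref
  class(out) <- c("ablation_study", "data.frame")
  out
}

#' @export
print.ablation_study <- function(x, ...) {
  cat("Sensor-ablation study (held-out windows)\n")
  y <- as.data.frame(x)
  y[, sapply(y, is.numeric)] <- round(y[, sapply(y, is.numeric)], 3)
  print(y, row.names = FALSE)
  invisible(x)
}
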