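#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i - 1` predicted
#' as class `j - 1` (rows = truth, columns = prediction).
#'
#' @param true_labels,predicted_labels equal-length vectors of 0-based ids.
#' @param num_classes number of classes `C`.
#' @param class_names optional vocabulary (defaults to `class0`, ...).
#' @return a `leafcnn_confusion` with fields `counts` (C x C integer matrix)
#'   and `class_names`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, num_classes,
                             class_names = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop_leafcnn("label vectors must have equal length")
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (anyNA(c(true_labels, predicted_labels)) ||
      any(c(true_labels, predicted_labels) < 0) ||
      any(c(true_labels, predicted_labels) >= num_classes))
    stop_leafcnn("labels must lie in [0, num_classes)")
  if (is.null(class_names))
    class_names <- sprintf("class%d", seq_len(num_classes) - 1L)
  counts <- matrix(0L, num_classes, num_classes,
                   dimnames = list(true = class_names, pred = class_names))
  for (k in seq_along(true_labels))
    counts[true_labels[k] + 1L, predicted_labels[k] + 1L] <-
      counts[true_labels[k] + 1L, predicted_labels[k] + 1L] + 1L
  structure(list(counts = counts, class_names = class_names),
            class = "leafcnn_confusion")
}

#' @export
print.leafcnn_confusion <- function(x, ...) {
  cat(sprintf("<confusion matrix: %d classes, %d samples>\n",
              nrow(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' One-vs-rest counts for a class
#'
#' Collapses the multiclass confusion matrix to the 2x2 table for class
#' `class_id`: `TP` is the diagonal cell, `FN` the rest of its row, `FP` the
#' rest of its column, and `TN` everything else.
#'
#' @param cm a `leafcnn_confusion`.
#' @param class_id 0-based class id.
#' @return named numeric vector `c(TP, FP, FN, TN)`.
#' @export
per_class_counts <- function(cm, class_id) {
  stopifnot(inherits(cm, "leafcnn_confusion"))
  C <- nrow(cm$counts)
  if (!is_count(class_id + 1, 1) || class_id >= C)
    stop_leafcnn("class_id must be a 0-based id < ", C)
  i <- class_id + 1L
  tp <- cm$counts[i, i]
  fn <- sum(cm$counts[i, ]) - tp
  fp <- sum(cm$counts[, i]) - tp
  tn <- sum(cm$counts) - tp - fn - fp
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Macro metric suite from a confusion matrix
#'
#' Per class `c`: recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1 the
#' harmonic mean of the two, and one-vs-rest accuracy `(TP+TN)/total`. Macro
#' recall/precision/F1 are the unweighted means over classes, and "mean
#' accuracy" is the mean of the per-class one-vs-rest accuracies — in
#' multiclass problems this is inflated by true negatives relative to macro
#' recall, which is why published mean accuracies sit near 99% alongside
#' 87-96% macro recalls. A class that is never predicted has undefined
#' precision; it is reported as 0 with a warning so macro averages remain
#' defined. All values are fractions in `[0, 1]`; see
#' [format_metric_report()] for the percent presentation.
#'
#' @param cm a `leafcnn_confusion` with at least one sample.
#' @return a `leafcnn_metrics` list: `per_class` data frame (recall,
#'   precision, f1, accuracy per class), `macro_recall`, `macro_precision`,
#'   `macro_f1`, `mean_accuracy`, `overall_accuracy`.
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "leafcnn_confusion"))
  total <- sum(cm$counts)
  if (total == 0) stop_leafcnn("empty confusion matrix")
  C <- nrow(cm$counts)
  rec <- prec <- f1 <- acc <- numeric(C)
  for (k in seq_len(C)) {
    ct <- per_class_counts(cm, k - 1L)
    rec[k] <- if (ct["TP"] + ct["FN"] > 0) ct["TP"] / (ct["TP"] + ct["FN"]) else 0
    if (ct["TP"] + ct["FP"] > 0) {
      prec[k] <- ct["TP"] / (ct["TP"] + ct["FP"])
    } else {
      prec[k] <- 0
      warning("class ", cm$class_names[k],
              " was never predicted; precision reported as 0")
    }
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    acc[k] <- (ct["TP"] + ct["TN"]) / total
  }
  structure(list(
    per_class = data.frame(class = cm$class_names, recall = rec,
                           precision = prec, f1 = f1, accuracy = acc,
                           stringsAsFactors = FALSE),
    macro_recall = mean(rec), macro_precision = mean(prec),
    macro_f1 = mean(f1), mean_accuracy = mean(acc),
    overall_accuracy = sum(diag(cm$counts)) / total),
    class = "leafcnn_metrics")
}

#' @export
print.leafcnn_metrics <- function(x, ...) {
  cat(sprintf(paste0("<metrics: macro recall %.2f%%, macro precision %.2f%%, ",
                     "macro F1 %.2f%%, mean accuracy %.2f%%>\n"),
              100 * x$macro_recall, 100 * x$macro_precision,
              100 * x$macro_f1, 100 * x$mean_accuracy))
  invisible(x)
}

#' Format a metric report as percentages
#'
#' @param metrics a `leafcnn_metrics`.
#' @return a data frame with one row per class plus a `macro` row, values as
#'   percentages rounded to 2 decimals.
#' @export
format_metric_report <- function(metrics) {
  stopifnot(inherits(metrics, "leafcnn_metrics"))
  pc <- metrics$per_class
  out <- data.frame(
    class = c(pc$class, "macro"),
    recall = round(100 * c(pc$recall, metrics$macro_recall), 2),
    precision = round(100 * c(pc$precision, metrics$macro_precision), 2),
    f1 = round(100 * c(pc$f1, metrics$macro_f1), 2),
    accuracy = round(100 * c(pc$accuracy, metrics$mean_accuracy), 2),
    stringsAsFactors = FALSE)
  out
}

#' Write metric report and confusion matrix artifacts
#'
#' @param metrics a `leafcnn_metrics`.
#' @param cm a `leafcnn_confusion`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_evaluation <- function(metrics, cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(format_metric_report(metrics),
            file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_class = metrics$per_class,
         macro_recall = metrics$macro_recall,
         macro_precision = metrics$macro_precision,
         macro_f1 = metrics$macro_f1,
         mean_accuracy = metrics$mean_accuracy,
         overall_accuracy = metrics$overall_accuracy),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(cm$counts), file.path(dir, "confusion.csv"))
  invisible(dir)
}

#' Per-class validation accuracy on a held-out set
#'
#' Mirrors the published per-species validation tables: for each class, the
#' percentage of its holdout images predicted correctly. Classes absent from
#' the holdout are reported as `NA` (missing), not 0.
#'
#' @param model a trained `leafcnn_network`.
#' @param holdout a nonempty `leafcnn_image_set`.
#' @return data frame with `class`, `n`, `correct`, `accuracy_percent`.
#' @export
per_class_validation_table <- function(model, holdout) {
  stopifnot(inherits(holdout, "leafcnn_image_set"))
  if (length(holdout$images) == 0) stop_leafcnn("holdout set is empty")
  pred <- predict_classes(model, holdout)$labels
  C <- length(holdout$class_names)
  out <- data.frame(class = holdout$class_names, n = 0L, correct = 0L,
                    accuracy_percent = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(C)) {
    idx <- holdout$labels == k - 1L
    out$n[k] <- sum(idx)
    if (out$n[k] > 0) {
      out$correct[k] <- sum(pred[idx] == k - 1L)
      out$accuracy_percent[k] <- round(100 * out$correct[k] / out$n[k], 2)
    }
  }
  out
}
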