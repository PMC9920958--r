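#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes:
#' `counts[i, j] = #(true = i & predicted = j)`.
#'
#' @param y_true,y_pred equal-length integer label vectors with values in
#'   `1..n_classes`.
#' @param n_classes number of classes (default 12).
#' @return A `confusion_matrix` (integer matrix).
#' @export
confusion <- function(y_true, y_pred, n_classes = 12L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  bad <- which(y_true < 1L | y_true > n_classes |
                 y_pred < 1L | y_pred > n_classes | is.na(y_true) | is.na(y_pred))
  if (length(bad)) {
    stop("label out of range 1..", n_classes, " at index ", bad[1L])
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class one-vs-rest metrics and macro averages
#'
#' For each class c the multi-class confusion matrix is collapsed
#' one-vs-rest (TP = cm[c,c]; FN = rest of row c; FP = rest of column c;
#' TN = everything else) and the usual ratios computed: accuracy
#' `(TP+TN)/N`, precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, F1 `2PR/(P+R)`. Ratios with a zero
#' denominator are reported as 0 and flagged, so macro averages (the
#' unweighted mean over classes) stay defined. All metrics are percentages.
#'
#' @param cm a [confusion()] matrix.
#' @return A `metrics_report` list: `per_class` data.frame (`class`,
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`, `support`,
#'   `undefined` flag), `macro` named vector, `n` total count.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  n_classes <- nrow(cm)
  N <- sum(cm)
  if (N == 0L) stop("empty confusion matrix")
  rows <- lapply(seq_len(n_classes), function(c) {
    TP <- cm[c, c]
    FN <- sum(cm[c, ]) - TP
    FP <- sum(cm[, c]) - TP
    TN <- N - TP - FN - FP
    safe <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
    acc <- c((TP + TN) / N, FALSE)
    pre <- safe(TP, TP + FP)
    rec <- safe(TP, TP + FN)
    spe <- safe(TN, TN + FP)
    f1 <- if (pre[1] + rec[1] == 0) c(0, TRUE) else
      c(2 * pre[1] * rec[1] / (pre[1] + rec[1]), FALSE)
    data.frame(class = c,
               accuracy = 100 * acc[1], precision = 100 * pre[1],
               recall = 100 * rec[1], specificity = 100 * spe[1],
               f1 = 100 * f1[1], support = TP + FN,
               undefined = any(c(pre[2], rec[2], spe[2], f1[2]) == 1))
  })
  per_class <- do.call(rbind, rows)
  macro <- colMeans(per_class[, c("accuracy", "precision", "recall",
                                  "specificity", "f1")])
  structure(list(per_class = per_class, macro = macro, n = N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  df <- x$per_class
  num <- c("accuracy", "precision", "recall", "specificity", "f1")
  df[num] <- lapply(df[num], round, digits)
  print(df[, c("class", num, "support")], row.names = FALSE)
  cat(sprintf(
    "macro: acc %.2f  prec %.2f  rec %.2f  spec %.2f  f1 %.2f  (n = %d)\n",
    x$macro["accuracy"], x$macro["precision"], x$macro["recall"],
    x$macro["specificity"], x$macro["f1"], x$n))
  invisible(x)
}

#' Compare two evaluation reports (e.g. balanced vs unbalanced training)
#'
#' Reports macro-metric deltas `b - a` and per-class recall deltas, the
#' quantities used to judge whether augmentation helped: positive deltas
#' mean run `b` (typically the augmented arm) improved on run `a`.
#'
#' @param report_a,report_b two [per_class_metrics()] reports over the
#'   same class set.
#' @return A `run_comparison` list: `macro_delta` named vector,
#'   `recall_delta` data.frame (`class`, `recall_a`, `recall_b`, `delta`).
#' @export
compare_runs <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "metrics_report"),
            inherits(report_b, "metrics_report"))
  if (!identical(report_a$per_class$class, report_b$per_class$class)) {
    stop("reports cover different class sets")
  }
  macro_delta <- report_b$macro - report_a$macro
  recall_delta <- data.frame(
    class = report_a$per_class$class,
    recall_a = report_a$per_class$recall,
    recall_b = report_b$per_class$recall)
  recall_delta$delta <- recall_delta$recall_b - recall_delta$recall_a
  structure(list(macro_delta = macro_delta, recall_delta = recall_delta),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("macro metric deltas (b - a):\n")
  print(round(x$macro_delta, 2))
  cat("per-class recall deltas:\n")
  print(transform(x$recall_delta,
                  recall_a = round(recall_a, 2),
                  recall_b = round(recall_b, 2),
                  delta = round(delta, 2)), row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV (metrics as rows, classes as columns)
#'
#' @param report a [per_class_metrics()] report.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- report$per_class
  metrics <- c("accuracy", "precision", "recall", "specificity", "f1")
  wide <- t(as.matrix(df[, metrics]))
  wide <- cbind(round(wide, 2), Average = round(unname(report$macro[metrics]), 2))
  out <- data.frame(Metric = c(metrics, "support"),
                    rbind(wide, c(df$support, sum(df$support))),
                    check.names = FALSE)
  names(out) <- c("Metric", df$class, "Average")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot a confusion matrix heat map
#' @param x a [confusion()] matrix.
#' @param ... unused.
#' @export
plot.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  n <- nrow(m)
  image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
        xlab = "predicted", ylab = "true", axes = FALSE,
        main = "confusion matrix")
  axis(1, at = seq_len(n), labels = seq_len(n))
  axis(2, at = seq_len(n), labels = rev(seq_len(n)))
  invisible(x)
}
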