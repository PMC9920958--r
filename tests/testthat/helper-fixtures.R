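# Small in-code fixtures shared across tests.

# a pose sequence with smoothly varying coordinates and constant label
make_seq <- function(n = 40L, label = 6L, source = "fix", seed = 1L,
                     frame = seq_len(n) - 1L) {
  set.seed(seed)
  base <- matrix(runif(51, 100, 300), n, 51, byrow = TRUE)
  drift <- outer(seq_len(n) / 10, rep(1, 51))
  attrs <- base + drift
  attrs[, seq(3, 51, by = 3)] <- matrix(runif(n * 17, 0.5, 1), n, 17)
  pose_sequence(attrs, frame = frame, label = label, source = source)
}

# an AlphaPose-style detection record
det_record <- function(frame, xy = 1:34, score = 0.9) {
  kp <- numeric(51)
  kp[setdiff(seq_len(51), seq(3, 51, by = 3))] <- xy
  kp[seq(3, 51, by = 3)] <- score
  list(image_id = paste0(frame, ".jpg"), keypoints = kp, score = 1)
}

# a small window table with labels, for split/scaler tests
make_windows <- function(n_per_class = 20L, classes = 1:4, seed = 2L) {
  set.seed(seed)
  rows <- lapply(classes, function(cl) {
    f <- matrix(rnorm(n_per_class * 153, mean = cl * 10), n_per_class)
    df <- as.data.frame(f)
    names(df) <- feature_names()
    cbind(data.frame(label = cl), df,
          data.frame(window_start = seq_len(n_per_class),
                     source = sprintf("s%d-%d", cl,
                                      rep(1:4, length.out = n_per_class))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# independent one-vs-rest metrics oracle: plain counting, no shared code
# with per_class_metrics beyond arithmetic
oracle_metrics <- function(y_true, y_pred, n_classes) {
  res <- lapply(seq_len(n_classes), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    div <- function(a, b) if (b == 0) 0 else a / b
    p <- div(tp, tp + fp); r <- div(tp, tp + fn)
    c(accuracy = 100 * (tp + tn) / length(y_true),
      precision = 100 * p, recall = 100 * r,
      specificity = 100 * div(tn, tn + fp),
      f1 = 100 * if (p + r == 0) 0 else 2 * p * r / (p + r),
      support = tp + fn)
  })
  do.call(rbind, res)
}
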