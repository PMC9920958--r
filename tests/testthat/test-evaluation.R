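test_that("confusion matrix counts true/predicted pairs and validates labels", {
  cm <- confusion(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  expect_equal(unclass(cm)[1, ], c(`1` = 1L, `2` = 1L))
  expect_equal(unclass(cm)[2, ], c(`1` = 0L, `2` = 1L))

  perfect <- confusion(1:4, 1:4, 4)
  expect_equal(unname(diag(unclass(perfect))), rep(1L, 4))
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)

  expect_error(confusion(c(1, 13), c(1, 1), 12), "index 2")

  set.seed(31)
  y <- sample(1:12, 1000, replace = TRUE)
  p <- sample(1:12, 1000, replace = TRUE)
  expect_equal(sum(unclass(confusion(y, p, 12))), 1000L)
})

test_that("one-vs-rest metrics match a hand-computed oracle on the reference matrix", {
  # 2-class matrix [[8,2],[1,9]]
  cm <- confusion(c(rep(1, 10), rep(2, 10)),
                  c(rep(1, 8), rep(2, 2), 1, rep(2, 9)), 2)
  rep <- per_class_metrics(cm)
  c1 <- rep$per_class[1, ]
  expect_equal(c1$precision, 88.89, tolerance = 1e-4)
  expect_equal(c1$recall, 80.00)
  expect_equal(c1$specificity, 90.00)
  expect_equal(c1$accuracy, 85.00)
  expect_equal(c1$f1, 84.21, tolerance = 1e-4)
  expect_equal(c1$support, 10)
})

test_that("metrics agree with the independent oracle on random matrices", {
  set.seed(77)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(20:80, 1)
    y <- sample(seq_len(k), n, replace = TRUE)
    p <- sample(seq_len(k), n, replace = TRUE)
    got <- per_class_metrics(confusion(y, p, k))
    want <- oracle_metrics(y, p, k)
    expect_equal(as.matrix(got$per_class[, colnames(want)]), want,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unname(got$macro),
                 unname(colMeans(want[, 1:5, drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("identity confusion gives 100% everywhere; zero support flags but stays 0", {
  cm <- confusion(rep(1:3, each = 4), rep(1:3, each = 4), 3)
  rep <- per_class_metrics(cm)
  expect_true(all(as.matrix(rep$per_class[, 2:6]) == 100))

  # class 3 never occurs and is never predicted
  cm2 <- confusion(c(1, 1, 2, 2), c(1, 1, 2, 2), 3)
  rep2 <- per_class_metrics(cm2)
  expect_equal(rep2$per_class$recall[3], 0)
  expect_true(rep2$per_class$undefined[3])
  expect_equal(rep2$per_class$support[3], 0)
  expect_equal(sum(rep2$per_class$support), 4)
})

test_that("metrics are invariant under consistent class relabeling", {
  set.seed(5)
  y <- sample(1:4, 200, replace = TRUE)
  p <- sample(1:4, 200, replace = TRUE)
  perm <- c(3L, 1L, 4L, 2L)
  a <- per_class_metrics(confusion(y, p, 4))
  b <- per_class_metrics(confusion(perm[y], perm[p], 4))
  reorder <- order(perm)
  expect_equal(a$per_class$recall, b$per_class$recall[perm])
  expect_equal(unname(a$macro), unname(b$macro))
  expect_equal(sum(a$per_class$support), a$n)
})

test_that("micro accuracy equals trace over total", {
  set.seed(6)
  y <- sample(1:5, 300, replace = TRUE)
  p <- ifelse(runif(300) < 0.6, y, sample(1:5, 300, replace = TRUE))
  cm <- confusion(y, p, 5)
  expect_equal(sum(diag(unclass(cm))) / sum(unclass(cm)), mean(y == p))
})

test_that("run comparison reports macro deltas and per-class recall deltas", {
  set.seed(8)
  y <- rep(1:3, each = 30)
  p1 <- ifelse(runif(90) < 0.7, y, sample(1:3, 90, replace = TRUE))
  p2 <- ifelse(runif(90) < 0.9, y, sample(1:3, 90, replace = TRUE))
  a <- per_class_metrics(confusion(y, p1, 3))
  b <- per_class_metrics(confusion(y, p2, 3))
  self_cmp <- compare_runs(a, a)
  expect_true(all(self_cmp$macro_delta == 0))
  expect_true(all(self_cmp$recall_delta$delta == 0))
  cmp <- compare_runs(a, b)
  expect_equal(unname(cmp$macro_delta["accuracy"]),
               unname(b$macro["accuracy"] - a$macro["accuracy"]))
  expect_equal(cmp$recall_delta$delta,
               b$per_class$recall - a$per_class$recall)
})

test_that("metrics CSV lays out metrics as rows and classes as columns", {
  cm <- confusion(rep(1:3, each = 5), rep(c(1, 2, 3), 5), 3)
  rep <- per_class_metrics(cm)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, path)
  got <- read.csv(path, check.names = FALSE)
  expect_equal(got$Metric,
               c("accuracy", "precision", "recall", "specificity", "f1",
                 "support"))
  expect_equal(names(got), c("Metric", "1", "2", "3", "Average"))
  expect_equal(got$Average[6], sum(rep$per_class$support))
})
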