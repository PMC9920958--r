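test_that("scaler finds the global scalar min and max of the fitted table", {
  p <- fit_scaler(matrix(0:100, ncol = 1))
  expect_equal(p$f_min, 0)
  expect_equal(p$f_max, 100)
  p2 <- fit_scaler(c(-5, 3))
  expect_equal(c(p2$f_min, p2$f_max), c(-5, 3))
  expect_error(fit_scaler(rep(2, 10)), "degenerate")
  expect_error(fit_scaler(c(1, NA)), "non-finite")

  # train scope vs all scope differ when the test split extends the range
  train <- matrix(runif(50, 0, 1), 10)
  test <- matrix(runif(25, 0, 2), 5)
  p_train <- fit_scaler(train, fit_scope = "train")
  p_all <- fit_scaler(rbind(train, test), fit_scope = "all")
  expect_equal(p_train$f_max, max(train))
  expect_equal(p_all$f_max, max(rbind(train, test)))
  expect_gt(p_all$f_max, p_train$f_max)
})

test_that("min-max mapping sends f_min to 0, f_max to the vocabulary top, midpoints by flooring", {
  p <- fit_scaler(c(0, 100))
  expect_equal(tokenize_values(0, p), 0L)
  expect_equal(tokenize_values(100, p), 30000L)
  expect_equal(tokenize_values(50, p), 15000L)
  p01 <- fit_scaler(c(0, 1))
  expect_equal(tokenize_values(0.005, p01), 150L)
  expect_error(tokenize_values(NaN, p01), "non-finite")
})

test_that("tokenizer is monotone, bounded, clamps idempotently and resolves distinct values", {
  set.seed(4)
  p <- fit_scaler(c(-3, 7))
  x <- sort(runif(1e5, -5, 9))            # includes out-of-range values
  id <- tokenize_values(x, p)
  expect_true(all(diff(id) >= 0))         # monotone
  expect_true(all(id >= 0 & id <= 30000)) # bounded
  # clamping: anything beyond f_max maps exactly like f_max
  expect_equal(unique(id[x > 7]), 30000L)
  expect_equal(unique(id[x < -3]), 0L)
  # resolution: gaps above one bin width always separate ids
  step <- (p$f_max - p$f_min) / p$vocab_numeric
  xs <- seq(-3, 7 - 2 * step, length.out = 500)
  expect_true(all(tokenize_values(xs + 1.5 * step, p) > tokenize_values(xs, p)))
})

test_that("windows encode as [CLS] + 153 numeric ids + [SEP] with full attention", {
  w <- make_windows(n_per_class = 2L, classes = 1:2)
  p <- fit_scaler(w)
  tok <- encode_windows(w, p)
  expect_equal(dim(tok$ids), c(4, 155))
  sp <- special_tokens(p)
  expect_true(all(tok$ids[, 1] == sp[["cls"]]))
  expect_true(all(tok$ids[, 155] == sp[["sep"]]))
  expect_true(all(tok$ids[, 2:154] >= 0 & tok$ids[, 2:154] <= 30000))
  expect_true(all(tok$attention_mask == 1))
  expect_equal(tok$vocab_size, 30004)

  # all-minimum window maps to all-zero numeric ids
  wmin <- matrix(p$f_min, 1, 153)
  tmin <- encode_windows(wmin, p)
  expect_equal(unname(tmin$ids[1, 2:154]), rep(0L, 153))

  # monotone features give monotone numeric ids
  mono <- matrix(seq(p$f_min, p$f_max, length.out = 153), 1)
  tm <- encode_windows(mono, p, add_special = FALSE)
  expect_true(all(diff(tm$ids[1, ]) >= 0))
})

test_that("scaler parameters persist through JSON exactly", {
  p <- fit_scaler(matrix(c(-1.25, 3.5, 0.1, 2), 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_scaler(p, path)
  p2 <- read_scaler(path)
  expect_equal(p2, p)
})
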