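test_that("window counts follow floor((N - W)/stride) + 1 and features have length 153", {
  spec <- window_spec()
  w36 <- build_windows(make_seq(36L), spec)
  expect_equal(nrow(w36), 1)
  expect_length(grep("^f[0-9]+$", names(w36)), 153)

  expect_equal(nrow(build_windows(make_seq(35L), spec)), 0)
  expect_equal(nrow(build_windows(make_seq(40L), spec)), 5)

  # property over random (N, stride)
  set.seed(9)
  for (i in 1:12) {
    n <- sample(36:90, 1); stride <- sample(1:5, 1)
    got <- nrow(build_windows(make_seq(n), window_spec(stride = stride)))
    expect_equal(got, floor((n - 36) / stride) + 1)
  }
})

test_that("feature vectors concatenate the selected frames frame-major", {
  s <- make_seq(40L)
  attrs <- as.matrix(as.data.frame(s)[, pose_attribute_names()])
  w <- build_windows(s, window_spec())
  # window k starts at frame k-1 (stride 1); offsets 0, 17, 35
  for (k in c(1, 5)) {
    expected <- c(attrs[k, ], attrs[k + 17, ], attrs[k + 35, ])
    expect_equal(unname(unlist(w[k, feature_names()])), unname(expected))
  }
  expect_equal(w$window_start, 0:4)
})

test_that("shifting frame indices shifts window_start identically", {
  s1 <- make_seq(50L)
  s2 <- make_seq(50L, frame = seq_len(50L) + 99L)
  spec <- window_spec(stride = 2L)
  w1 <- build_windows(s1, spec)
  w2 <- build_windows(s2, spec)
  expect_equal(w2$window_start - w1$window_start,
               rep(100L, nrow(w1)))
  expect_equal(window_features(w1), window_features(w2))
})

test_that("window labels use majority with last-frame tie-break", {
  expect_equal(assign_label(rep(6L, 36)), 6L)
  expect_equal(assign_label(c(rep(7L, 18), rep(8L, 18))), 8L)
  expect_equal(assign_label(c(rep(3L, 20), rep(11L, 16))), 3L)
  # missing labels fall back to the labeled frames
  expect_equal(assign_label(c(NA, NA, 4L, NA)), 4L)
  expect_true(is.na(assign_label(rep(NA_integer_, 5))))
  expect_equal(assign_label(c(rep(2L, 10), rep(9L, 10)), rule = "last"), 9L)
})

test_that("windows spanning missing frames are dropped (or imputed with locf)", {
  s <- make_seq(45L)
  gap <- as.data.frame(s)[-20, ]          # remove frame 19
  s_gap <- pose_sequence(as.matrix(gap[, pose_attribute_names()]),
                         frame = gap$frame, label = gap$label,
                         source = gap$source)
  w <- build_windows(s_gap, window_spec())
  # every start in 0..9 covers frame 19 except none (0..9 all cover 19);
  # usable windows start only after the gap or not at all
  expect_true(all(w$window_start > 19 - 36 + 35))
  expect_gt(attr(w, "n_dropped"), 0)

  w_locf <- build_windows(s_gap, window_spec(missing = "locf"))
  expect_equal(nrow(w_locf), 10)          # full grid length 45 -> 10 windows
  expect_equal(attr(w_locf, "n_dropped"), 0)
})

test_that("window spec validates offsets and stride", {
  expect_error(window_spec(selected_offsets = c(0, 36, 35)))
  expect_error(window_spec(selected_offsets = c(5, 5, 6)), "increasing")
  expect_error(window_spec(stride = 0))
})
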