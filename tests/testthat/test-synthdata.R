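test_that("generation honours per-class counts and is bit-reproducible", {
  mc <- motion_config(c(`1` = 3L, `6` = 10L), seed = 5)
  d1 <- generate_dataset(mc)
  expect_length(d1, 13)
  labs <- vapply(d1, function(s) s$label[1], integer(1))
  expect_equal(sum(labs == 1), 3)
  expect_equal(sum(labs == 6), 10)
  d2 <- generate_dataset(mc)
  expect_identical(d1, d2)
  # sources are unique
  srcs <- vapply(d1, function(s) s$source[1], character(1))
  expect_equal(anyDuplicated(srcs), 0)
})

test_that("generated sequences satisfy pose validation and the CSV dialect", {
  d <- generate_dataset(motion_config(c(`3` = 1L, `8` = 1L), seed = 2))
  for (s in d) {
    expect_s3_class(s, "pose_sequence")
    scores <- as.matrix(as.data.frame(s)[, paste0("s", 1:17)])
    expect_true(all(scores >= 0 & scores <= 1))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(d[[1]], path)
  expect_identical(as.data.frame(read_pose_csv(path)), as.data.frame(d[[1]]))
})

test_that("fall sequences descend: head y grows from first to last frame", {
  mc <- motion_config(setNames(rep(10L, 5), 1:5), seconds = 2.5, seed = 9)
  d <- generate_dataset(mc)
  drops <- vapply(d, function(s) {
    df <- as.data.frame(s)
    df$y1[nrow(df)] - df$y1[1]          # nose y, image coords point down
  }, numeric(1))
  expect_gt(mean(drops > 0), 0.95)
})

test_that("near-zero noise without jitter makes classes nearest-centroid separable", {
  counts <- setNames(rep(4L, 12), 1:12)
  d <- generate_dataset(motion_config(counts, seconds = 2, noise_sd = 0.1,
                                      jitter = FALSE, seed = 3))
  win <- build_windows_all(d, window_spec())   # 36 frames -> 1 window/sequence
  feats <- window_features(win)
  scols <- seq(3, 153, by = 3)
  feats <- feats[, -scols]              # scores are class-uninformative
  centroids <- aggregate(feats, list(label = win$label), mean)
  cl <- as.matrix(centroids[, -1])
  pred <- centroids$label[apply(feats, 1, function(r) {
    which.min(colSums((t(cl) - r)^2))
  })]
  expect_equal(mean(pred == win$label), 1)
})

test_that("imbalance profiles allocate the budget exactly", {
  u <- imbalance_profile("uniform", 120)
  expect_equal(unname(u), rep(10L, 12))

  p <- imbalance_profile("upfall_like", 10000)
  expect_equal(sum(p), 10000L)
  expect_equal(unname(p[["6"]]), 1859, tolerance = 0.001)  # walking share 18.59%
  expect_true(all(p[as.character(1:5)] < 100))             # each fall class < 1%
  expect_error(imbalance_profile("uniform", 5), "budget")

  # conservation for odd budgets
  for (b in c(123, 997, 5001)) {
    expect_equal(sum(imbalance_profile("upfall_like", b)), b)
  }
})

test_that("window budgets convert to sequence counts that can supply them", {
  wc <- c(`1` = 14L, `6` = 558L)
  sc <- sequences_for_windows(wc, seconds = 2.5, fps = 18,
                              spec = window_spec(stride = 2L))
  # 45 frames -> 5 windows per sequence
  expect_equal(unname(sc), c(3L, 112L))
})
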