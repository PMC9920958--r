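test_that("a detection frame flattens to 51 attributes in (x, y, score) order", {
  kp <- cbind(x = 1:17 * 10, y = 1:17 * 20, score = seq(0.1, 0.9, length.out = 17))
  v <- flatten_frame(kp)
  expect_length(v, 51)
  expect_equal(v[1:3], c(10, 20, 0.1))
  expect_equal(v[49:51], unname(c(170, 340, 0.9)))
  # round-trip
  expect_equal(unname(frame_keypoints(v)), unname(kp))
  expect_equal(flatten_frame(matrix(0, 17, 3)), rep(0, 51))
})

test_that("pose sequences validate joint count, scores, labels and ordering", {
  expect_error(pose_sequence(matrix(0, 2, 50)), "51")
  bad_score <- matrix(0, 2, 51); bad_score[1, 3] <- 1.5
  expect_error(pose_sequence(bad_score), "scores")
  ok <- matrix(0.5, 2, 51)
  expect_error(pose_sequence(ok, frame = c(3, 3)), "increasing")
  expect_error(pose_sequence(ok, label = 13L), "1..12", fixed = TRUE)
  s <- pose_sequence(ok, label = 12L)
  expect_s3_class(s, "pose_sequence")
  expect_equal(attr(s, "fps"), 18)
})

test_that("AlphaPose-style JSON is parsed, keeping the best detection per frame", {
  path <- withr::local_tempfile(fileext = ".json")
  # frame 0: two detections, mean keypoint scores 0.4 and 0.9
  recs <- list(det_record(0, xy = 1:34, score = 0.4),
               det_record(0, xy = 101:134, score = 0.9),
               det_record(1, xy = 51:84, score = 0.7))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  s <- read_pose_json(path)
  expect_equal(nrow(s), 2)
  expect_equal(s$x1[1], 101)    # the 0.9 detection won
  expect_equal(s$frame, c(0L, 1L))

  # empty detection list
  jsonlite::write_json(list(), path)
  expect_equal(nrow(read_pose_json(path)), 0)

  # malformed keypoint arrays are named by record
  jsonlite::write_json(list(list(image_id = "0.jpg", keypoints = 1:10)),
                       path, auto_unbox = TRUE)
  expect_error(read_pose_json(path), "record 1.*length 10")
})

test_that("tied mean detection scores resolve to the first record", {
  path <- withr::local_tempfile(fileext = ".json")
  recs <- list(det_record(5, xy = 1:34, score = 0.8),
               det_record(5, xy = 101:134, score = 0.8))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  s <- read_pose_json(path)
  expect_equal(s$x1, 1)
})

test_that("pose CSV round-trips bit-exactly and validates its input", {
  s <- make_seq(n = 3L, label = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(s, path)
  s2 <- read_pose_csv(path)
  expect_identical(as.data.frame(s2), as.data.frame(s))

  # missing columns reported by name
  df <- read.csv(path)
  df$x3 <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_pose_csv(path), "x3")

  # out-of-range label
  s3 <- make_seq(n = 2L)
  write_pose_csv(s3, path)
  df <- read.csv(path)
  df$label <- 13
  write.csv(df, path, row.names = FALSE)
  expect_error(read_pose_csv(path), "1..12", fixed = TRUE)

  # non-numeric coordinate names the row
  write_pose_csv(s3, path)
  df <- read.csv(path)
  df$x1 <- as.character(df$x1); df$x1[2] <- "oops"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_pose_csv(path), "row 2")
})
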