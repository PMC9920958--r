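#' COCO-17 keypoint names
#'
#' Joint names in the fixed order used throughout the package. Pose
#' estimators pretrained on COCO emit 17 keypoints per person; each keypoint
#' carries an (x, y) image coordinate and a detection confidence score, so a
#' frame flattens to 51 attributes.
#'
#' @return Character vector of length 17.
#' @export
coco_keypoints <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

#' Flattened attribute column names
#'
#' The 51 per-frame attribute columns in their canonical interleaved order
#' `x1, y1, s1, ..., x17, y17, s17` (x = column coordinate, y = row
#' coordinate, s = confidence score of each COCO joint).
#'
#' @return Character vector of length 51.
#' @export
pose_attribute_names <- function() {
  as.vector(t(outer(1:17, c("x", "y", "s"), function(i, p) paste0(p, i))))
}

N_ATTRIBUTES <- 51L
N_CLASSES <- 12L

#' Construct a pose sequence
#'
#' A pose sequence is a data frame with one row per video frame: a `frame`
#' index, an activity `label` (class id 1-12 or NA), an optional `source`
#' identifier (subject/camera/trial), and the 51 flattened keypoint
#' attributes `x1, y1, s1, ..., x17, y17, s17`. Frames must be strictly
#' increasing in `frame`; gaps denote frames with no usable detection.
#'
#' @param attributes numeric matrix or data frame with 51 columns, one row
#'   per frame, in `pose_attribute_names()` order.
#' @param frame integer frame indices, strictly increasing, non-negative.
#' @param label integer class ids in 1..12, or NA when unlabeled.
#' @param source single string or per-frame character vector identifying the
#'   recording (defaults to `"seq"`).
#' @param fps frames per second of the recording (default 18, so that a
#'   36-frame window spans 2 seconds).
#' @return A `pose_sequence` (data.frame subclass) with attribute `fps`.
#' @export
pose_sequence <- function(attributes, frame = seq_len(nrow(attributes)) - 1L,
                          label = NA_integer_, source = "seq", fps = 18) {
  attributes <- as.matrix(attributes)
  if (ncol(attributes) != N_ATTRIBUTES) {
    stop("pose attributes must have exactly 51 columns (17 joints x (x,y,score)), got ",
         ncol(attributes))
  }
  n <- nrow(attributes)
  frame <- as.integer(frame)
  if (any(is.na(frame)) || any(frame < 0L)) {
    stop("frame indices must be non-negative integers")
  }
  if (n > 1L && any(diff(frame) <= 0L)) {
    stop("frame indices must be strictly increasing")
  }
  label <- as.integer(rep_len(label, n))
  bad <- !is.na(label) & (label < 1L | label > N_CLASSES)
  if (any(bad)) {
    stop("labels must be class ids in 1..12; offending value(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  if (!all(is.finite(attributes))) stop("keypoint attributes must be finite")
  s_cols <- seq(3L, N_ATTRIBUTES, by = 3L)
  s <- attributes[, s_cols, drop = FALSE]
  if (any(s < 0 | s > 1)) stop("keypoint scores must lie in [0, 1]")

  out <- data.frame(frame = frame, label = label,
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  attr_df <- as.data.frame(attributes)
  names(attr_df) <- pose_attribute_names()
  out <- cbind(out, attr_df)
  attr(out, "fps") <- fps
  class(out) <- c("pose_sequence", "data.frame")
  out
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("pose_sequence: %d frames @ %g fps, source(s): %s\n",
              nrow(x), attr(x, "fps"),
              paste(unique(x$source), collapse = ", ")))
  labs <- unique(x$label[!is.na(x$label)])
  cat(sprintf("  labels: %s\n",
              if (length(labs)) paste(sort(labs), collapse = ", ") else "<none>"))
  invisible(x)
}

#' Flatten one pose frame to its 51-attribute vector
#'
#' @param keypoints a 17 x 3 matrix (columns x, y, score), or a single row
#'   of a `pose_sequence`.
#' @return Numeric vector of length 51 in `x1, y1, s1, ...` order.
#' @seealso [frame_keypoints()] for the inverse.
#' @export
flatten_frame <- function(keypoints) {
  if (is.data.frame(keypoints)) {
    stopifnot(nrow(keypoints) == 1L)
    return(as.numeric(keypoints[1L, pose_attribute_names()]))
  }
  keypoints <- as.matrix(keypoints)
  if (!identical(dim(keypoints), c(17L, 3L))) {
    stop("expected a 17 x 3 keypoint matrix")
  }
  as.vector(t(keypoints))
}

#' Reshape a 51-attribute vector back to a 17 x 3 keypoint matrix
#'
#' @param attributes numeric vector of length 51.
#' @return 17 x 3 matrix with columns x, y, score and COCO joint rownames.
#' @export
frame_keypoints <- function(attributes) {
  if (length(attributes) != N_ATTRIBUTES) stop("expected 51 attributes")
  m <- matrix(attributes, ncol = 3L, byrow = TRUE,
              dimnames = list(coco_keypoints(), c("x", "y", "score")))
  m
}

#' Read pose detections from an AlphaPose-style JSON file
#'
#' Consumes the detection-list dialect written by multi-person pose
#' estimators: a JSON array of records, each with an `image_id` (or `frame`)
#' field, a flat `keypoints` array of 51 numbers (x, y, score interleaved),
#' and optionally an overall `score`. When a frame carries several
#' detections, the one with the highest mean keypoint score is kept (ties
#' broken by first occurrence); the retained detections are returned in
#' frame order.
#'
#' @param path path to the JSON file.
#' @param fps frames per second to record on the result (default 18).
#' @param source source identifier for the sequence (default the file name).
#' @return A [pose_sequence()] with NA labels.
#' @export
read_pose_json <- function(path, fps = 18, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(recs) == 0L) {
    return(pose_sequence(matrix(numeric(0), ncol = N_ATTRIBUTES),
                         frame = integer(0), label = integer(0),
                         source = character(0), fps = fps))
  }
  parse_rec <- function(r, i) {
    id <- r$image_id
    if (is.null(id)) id <- r$frame
    if (is.null(id)) stop("record ", i, " has neither image_id nor frame")
    # AlphaPose image ids look like "123.jpg"
    fr <- suppressWarnings(as.integer(sub("\\..*$", "", as.character(id))))
    if (is.na(fr)) stop("record ", i, ": cannot parse frame index from ", id)
    kp <- unlist(r$keypoints)
    if (length(kp) != N_ATTRIBUTES) {
      stop("record ", i, ": keypoint array has length ", length(kp),
           ", expected 51")
    }
    if (!all(is.finite(kp))) stop("record ", i, ": non-finite keypoints")
    list(frame = fr, kp = kp, mean_score = mean(kp[seq(3L, 51L, by = 3L)]))
  }
  parsed <- lapply(seq_along(recs), function(i) parse_rec(recs[[i]], i))
  frames <- vapply(parsed, `[[`, integer(1), "frame")
  scores <- vapply(parsed, `[[`, numeric(1), "mean_score")
  # highest mean keypoint score per frame; ties -> first occurrence
  keep <- vapply(split(seq_along(parsed), frames), function(idx) {
    idx[which.max(scores[idx])]
  }, integer(1))
  keep <- keep[order(frames[keep])]
  mat <- do.call(rbind, lapply(parsed[keep], `[[`, "kp"))
  pose_sequence(mat, frame = frames[keep], label = NA_integer_,
                source = source, fps = fps)
}

#' Read a pose sequence from CSV
#'
#' Expects the package's CSV dialect: header `frame,label,x1,y1,s1,...,
#' x17,y17,s17` with an optional `source` column after `label`. Labels may
#' be empty (NA) but must be class ids 1-12 when present.
#'
#' @param path path to the CSV file.
#' @param fps frames per second (default 18).
#' @return A [pose_sequence()].
#' @export
read_pose_csv <- function(path, fps = 18) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("frame", "label", pose_attribute_names())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  attr_cols <- pose_attribute_names()
  for (cn in c("frame", "label", attr_cols)) {
    v <- df[[cn]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop("non-numeric value in column '", cn, "' at row ", bad[1L])
      }
      df[[cn]] <- conv
    }
  }
  pose_sequence(as.matrix(df[, attr_cols]),
                frame = df$frame, label = df$label,
                source = if ("source" %in% names(df)) df$source else basename(path),
                fps = fps)
}

#' Write a pose sequence to CSV
#'
#' Inverse of [read_pose_csv()]; round-trips exactly.
#'
#' @param seq a [pose_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  df <- as.data.frame(seq)[, c("frame", "label", "source", pose_attribute_names())]
  # 17 significant digits so numeric attributes round-trip bit-exactly
  for (cn in pose_attribute_names()) df[[cn]] <- sprintf("%.17g", df[[cn]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
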