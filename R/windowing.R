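#' Sliding-window specification
#'
#' Defines how labeled feature windows are cut from a pose sequence. The
#' defaults mirror the 2-second protocol at 18 fps: 36 consecutive frames
#' per window, of which only the first, middle and last are retained, so
#' each window flattens to 3 x 51 = 153 features.
#'
#' @param window_frames window length in frames (default 36).
#' @param selected_offsets 0-based offsets of the frames kept within each
#'   window, strictly increasing (default `c(0, 17, 35)`; 17 is
#'   `floor((36 - 1) / 2)`, the middle of an even-length window).
#' @param stride step between consecutive window starts, in frames
#'   (default 1).
#' @param label_rule `"majority"` (most frequent frame label, ties broken by
#'   the last frame's label) or `"last"` (final frame's label).
#' @param missing `"drop"` (default): windows that span a frame with no
#'   detection are discarded and counted; `"locf"`: gaps are imputed by
#'   carrying the last observed frame forward.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_frames = 36L, selected_offsets = NULL,
                        stride = 1L, label_rule = c("majority", "last"),
                        missing = c("drop", "locf")) {
  window_frames <- as.integer(window_frames)
  if (is.null(selected_offsets)) {
    selected_offsets <- c(0L, (window_frames - 1L) %/% 2L, window_frames - 1L)
  }
  selected_offsets <- as.integer(selected_offsets)
  stride <- as.integer(stride)
  stopifnot(window_frames >= 1L, stride >= 1L,
            all(selected_offsets >= 0L),
            all(selected_offsets <= window_frames - 1L))
  if (any(diff(selected_offsets) <= 0L)) {
    stop("selected_offsets must be strictly increasing")
  }
  structure(list(window_frames = window_frames,
                 selected_offsets = selected_offsets,
                 stride = stride,
                 label_rule = match.arg(label_rule),
                 missing = match.arg(missing)),
            class = "window_spec")
}

#' Assign a single label to a window of frame labels
#'
#' @param frame_labels integer vector of class ids (NA allowed for frames
#'   whose label is missing).
#' @param rule `"majority"` or `"last"`. Under `"majority"` only labeled
#'   frames are counted and ties go to the last frame's (labeled) value;
#'   `"last"` returns the final frame's label.
#' @return A class id, or NA if no frame is labeled.
#' @export
assign_label <- function(frame_labels, rule = c("majority", "last")) {
  rule <- match.arg(rule)
  if (length(frame_labels) == 0L) stop("empty label vector")
  labs <- frame_labels[!is.na(frame_labels)]
  if (length(labs) == 0L) return(NA_integer_)
  if (rule == "last") return(as.integer(labs[length(labs)]))
  tab <- table(labs)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) return(top)
  last <- as.integer(labs[length(labs)])
  if (last %in% top) last else top[1L]
}

#' Feature column names for a window table
#' @param n number of features (default 153).
#' @return `f001 ... f153`-style names.
#' @export
feature_names <- function(n = 153L) sprintf("f%03d", seq_len(n))

#' Cut sliding feature windows from a pose sequence
#'
#' Slides a `window_frames`-long window along the sequence in steps of
#' `stride`, keeps the frames at `selected_offsets`, and concatenates their
#' 51-attribute vectors (frame-major) into one feature row per window. For a
#' gapless sequence of N frames the number of windows is
#' `floor((N - window_frames) / stride) + 1`; shorter sequences yield an
#' empty table. Gaps in the frame index are treated per `spec$missing`.
#'
#' @param seq a [pose_sequence()].
#' @param spec a [window_spec()].
#' @return A data.frame with columns `label`, `f001...f153` (or
#'   `51 * length(selected_offsets)` features), `window_start` (frame index
#'   of the first frame) and `source`; attribute `n_dropped` counts windows
#'   discarded because of missing frames or unlabeled content.
#' @export
build_windows <- function(seq, spec = window_spec()) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(spec, "window_spec"))
  W <- spec$window_frames
  nfeat <- length(spec$selected_offsets) * N_ATTRIBUTES

  empty <- function(n_dropped = 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = nfeat))
    names(out) <- feature_names(nfeat)
    out <- cbind(data.frame(label = integer(0)), out,
                 data.frame(window_start = integer(0), source = character(0),
                            stringsAsFactors = FALSE))
    attr(out, "n_dropped") <- n_dropped
    out
  }
  if (nrow(seq) == 0L) return(empty())

  # lay frames on the full index grid so gaps are visible
  f0 <- min(seq$frame)
  grid_len <- max(seq$frame) - f0 + 1L
  pos <- seq$frame - f0 + 1L
  present <- logical(grid_len)
  present[pos] <- TRUE
  row_at <- rep(NA_integer_, grid_len)
  row_at[pos] <- seq_len(nrow(seq))
  if (spec$missing == "locf") {
    last <- NA_integer_
    for (i in seq_len(grid_len)) {
      if (is.na(row_at[i])) row_at[i] <- last else last <- row_at[i]
    }
    present <- !is.na(row_at)
  }

  if (grid_len < W) return(empty())
  starts <- seq.int(1L, grid_len - W + 1L, by = spec$stride)
  attrs <- as.matrix(as.data.frame(seq)[, pose_attribute_names()])
  labels <- seq$label

  feats <- matrix(NA_real_, nrow = length(starts), ncol = nfeat)
  win_label <- integer(length(starts))
  keep <- logical(length(starts))
  n_dropped <- 0L
  for (k in seq_along(starts)) {
    span <- starts[k]:(starts[k] + W - 1L)
    if (!all(present[span])) { n_dropped <- n_dropped + 1L; next }
    rows <- row_at[span]
    lab <- assign_label(labels[rows], spec$label_rule)
    if (is.na(lab)) { n_dropped <- n_dropped + 1L; next }
    sel <- rows[spec$selected_offsets + 1L]
    feats[k, ] <- as.vector(t(attrs[sel, , drop = FALSE]))
    win_label[k] <- lab
    keep[k] <- TRUE
  }
  if (!any(keep)) return(empty(n_dropped))

  out <- as.data.frame(feats[keep, , drop = FALSE])
  names(out) <- feature_names(nfeat)
  out <- cbind(data.frame(label = win_label[keep]), out,
               data.frame(window_start = f0 + starts[keep] - 1L,
                          source = seq$source[row_at[starts[keep]]],
                          stringsAsFactors = FALSE))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Cut windows from many sequences and stack them
#'
#' @param seqs list of [pose_sequence()] objects.
#' @param spec a [window_spec()].
#' @return Stacked window table (see [build_windows()]); `n_dropped`
#'   attributes are summed.
#' @export
build_windows_all <- function(seqs, spec = window_spec()) {
  parts <- lapply(seqs, build_windows, spec = spec)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(vapply(parts, attr, integer(1), "n_dropped"))
  out
}

#' Extract the feature matrix from a window table
#' @param windows a window table from [build_windows()].
#' @return Numeric matrix (windows x features).
#' @export
window_features <- function(windows) {
  fcols <- grep("^f[0-9]+$", names(windows), value = TRUE)
  as.matrix(windows[, fcols, drop = FALSE])
}
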