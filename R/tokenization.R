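#' Fit the global min-max tokenization scaler
#'
#' The numeric tokenizer maps every continuous feature value F to an
#' integer token id
#' \deqn{id = \lfloor V (F - F_{min}) / (F_{max} - F_{min}) \rfloor}
#' where `F_min` and `F_max` are one global scalar minimum and maximum over
#' every cell of the fitted table (not per-feature), and V is the numeric
#' vocabulary span (default 30,000, so ids run 0...30,000). Values outside
#' `[F_min, F_max]` — possible when the scaler is fitted on the training
#' split only — are clamped to the boundary before flooring.
#'
#' @param x numeric matrix/data.frame of feature values (a window table's
#'   feature columns), or a numeric vector.
#' @param vocab_numeric vocabulary span V (default 30000).
#' @param fit_scope `"train"` (recommended: fit on the training split only)
#'   or `"all"` (fit on the entire dataset). Recorded for provenance; the
#'   caller supplies whichever data matches.
#' @return A `scaler_params` list: `f_min`, `f_max`, `vocab_numeric`,
#'   `fit_scope`.
#' @export
fit_scaler <- function(x, vocab_numeric = 30000L,
                       fit_scope = c("train", "all")) {
  fit_scope <- match.arg(fit_scope)
  if (is.data.frame(x)) x <- window_features(x)
  x <- as.numeric(as.matrix(x))
  if (length(x) == 0L) stop("cannot fit a scaler on an empty table")
  if (!all(is.finite(x))) stop("scaler input contains non-finite values")
  vocab_numeric <- as.integer(vocab_numeric)
  if (vocab_numeric < 2L) stop("vocab_numeric must be at least 2")
  f_min <- min(x); f_max <- max(x)
  if (f_max == f_min) {
    stop("degenerate scale: all values equal (f_min == f_max == ", f_min, ")")
  }
  structure(list(f_min = f_min, f_max = f_max,
                 vocab_numeric = vocab_numeric, fit_scope = fit_scope),
            class = "scaler_params")
}

#' @export
print.scaler_params <- function(x, ...) {
  cat(sprintf("min-max token scaler: F in [%g, %g] -> ids 0..%d (scope: %s)\n",
              x$f_min, x$f_max, x$vocab_numeric, x$fit_scope))
  invisible(x)
}

#' Map feature values to numeric token ids
#'
#' Applies the fitted min-max mapping: clamp to `[f_min, f_max]`, scale to
#' `[0, V]`, keep the integer part. `F = f_min` maps to 0 and `F = f_max`
#' to V (30,000 under defaults). Monotone: F1 <= F2 implies id1 <= id2.
#'
#' @param x numeric vector/matrix of feature values (finite).
#' @param params a [fit_scaler()] result.
#' @return Integer token ids with the shape of `x`, each in `[0, V]`.
#' @export
tokenize_values <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  if (!all(is.finite(x))) stop("cannot tokenize non-finite values")
  f <- pmin(pmax(x, params$f_min), params$f_max)
  # ratio first, so F = f_max gives exactly 1 and hence exactly V
  ratio <- (f - params$f_min) / (params$f_max - params$f_min)
  id <- floor(params$vocab_numeric * ratio)
  id <- pmin(pmax(id, 0), params$vocab_numeric)
  storage.mode(id) <- "integer"
  id
}

#' Special token ids for a scaler
#'
#' The numeric ids occupy `0..V`; the special tokens are appended after
#' them in a from-scratch embedding table: `[PAD] = V+1`, `[CLS] = V+2`,
#' `[SEP] = V+3`, giving a total vocabulary of `V+4`.
#'
#' @param params a [fit_scaler()] result.
#' @return Named integer vector `pad`, `cls`, `sep`, `vocab_size`.
#' @export
special_tokens <- function(params) {
  v <- params$vocab_numeric
  c(pad = v + 1L, cls = v + 2L, sep = v + 3L, vocab_size = v + 4L)
}

#' Encode feature windows as token-id sequences
#'
#' Tokenizes each of the 153 features in order and frames the result as
#' `[CLS], id_1, ..., id_153, [SEP]` (length 155 under defaults; the
#' framing can be disabled). No padding is needed at fixed length, so the
#' attention mask is all ones. Sequences must fit the encoder's 512-token
#' limit.
#'
#' @param features numeric matrix (windows x features), a window table, or
#'   a single numeric vector.
#' @param params a [fit_scaler()] result.
#' @param add_special prepend `[CLS]` and append `[SEP]` (default TRUE).
#' @return A `token_sequences` list: `ids` (integer matrix, one row per
#'   window), `attention_mask` (same shape, all ones), `vocab_size`.
#' @export
encode_windows <- function(features, params, add_special = TRUE) {
  if (is.data.frame(features)) features <- window_features(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  ids <- tokenize_values(features, params)
  sp <- special_tokens(params)
  if (add_special) {
    ids <- cbind(matrix(sp[["cls"]], nrow(ids), 1L), ids,
                 matrix(sp[["sep"]], nrow(ids), 1L))
  }
  if (ncol(ids) > 512L) {
    stop("token sequence length ", ncol(ids), " exceeds the 512-token limit")
  }
  structure(list(ids = ids,
                 attention_mask = matrix(1L, nrow(ids), ncol(ids)),
                 vocab_size = unname(sp[["vocab_size"]])),
            class = "token_sequences")
}

#' @export
print.token_sequences <- function(x, ...) {
  cat(sprintf("token_sequences: %d sequences of length %d (vocab %d)\n",
              nrow(x$ids), ncol(x$ids), x$vocab_size))
  invisible(x)
}

#' Persist / restore scaler parameters as JSON
#'
#' @param params a [fit_scaler()] result.
#' @param path file path for the small JSON artifact.
#' @return `path` (write) or a `scaler_params` object (read).
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "scaler_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(f_min = obj$f_min, f_max = obj$f_max,
                 vocab_numeric = as.integer(obj$vocab_numeric),
                 fit_scope = obj$fit_scope),
            class = "scaler_params")
}
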