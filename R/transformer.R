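#' Transformer encoder configuration
#'
#' Architecture of the sequence classifier: learned token + position
#' embeddings, a stack of post-norm encoder layers (multi-head
#' self-attention followed by a GELU feed-forward block, each with a
#' residual connection and layer norm), and a classification head (dropout
#' + linear) over the final-layer `[CLS]` embedding.
#'
#' Two presets are provided. `"base"` is the standard full-size encoder
#' (12 layers, 768 hidden, 12 heads, 3072 ffn; ~110M parameters at a
#' 30,004-token vocabulary) and is intended for full-scale runs only.
#' `"tiny"` (2 layers, 64 hidden, 4 heads, 128 ffn) trains in seconds to
#' minutes on a CPU and is the preset used throughout the package's tests
#' and synthetic benchmarks.
#'
#' @param preset `"tiny"` (default) or `"base"`; individual fields may be
#'   overridden.
#' @param layers,hidden,heads,ffn_dim encoder stack dimensions; `hidden`
#'   must be divisible by `heads`.
#' @param dropout_head dropout probability before the output linear layer
#'   (default 0.1; applied in training mode only).
#' @param n_classes number of activity classes (default 12).
#' @param max_len maximum token-sequence length (512).
#' @return A `model_config` list.
#' @export
model_config <- function(preset = c("tiny", "base"), layers = NULL,
                         hidden = NULL, heads = NULL, ffn_dim = NULL,
                         dropout_head = 0.1, n_classes = 12L,
                         max_len = 512L) {
  preset <- match.arg(preset)
  def <- if (preset == "base") {
    list(layers = 12L, hidden = 768L, heads = 12L, ffn_dim = 3072L)
  } else {
    list(layers = 2L, hidden = 64L, heads = 4L, ffn_dim = 128L)
  }
  cfg <- list(
    preset = preset,
    layers = as.integer(layers %||% def$layers),
    hidden = as.integer(hidden %||% def$hidden),
    heads = as.integer(heads %||% def$heads),
    ffn_dim = as.integer(ffn_dim %||% def$ffn_dim),
    dropout_head = dropout_head,
    n_classes = as.integer(n_classes),
    max_len = as.integer(max_len)
  )
  if (cfg$hidden %% cfg$heads != 0L) {
    stop("hidden (", cfg$hidden, ") must be divisible by heads (", cfg$heads, ")")
  }
  if (cfg$n_classes < 2L) stop("n_classes must be at least 2")
  structure(cfg, class = "model_config")
}

#' Training configuration for the classifier
#'
#' Defaults follow the published fine-tuning recipe: AdamW, learning rate
#' 2e-5, batch size 16, 20 epochs, and a 70/15/15 train/validation/test
#' split. When training the tiny preset from scratch a larger learning
#' rate (about 1e-3) is appropriate; the 2e-5 default is the fine-tuning
#' setting.
#'
#' @param epochs training epochs (default 20).
#' @param learning_rate AdamW learning rate (default 2e-5).
#' @param batch_size minibatch size (default 16).
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param split train/validation/test fractions, summing to 1.
#' @param split_mode `"window_random"` (stratified random windows, the
#'   published protocol) or `"grouped_by_source"` (whole recordings are
#'   assigned to one partition, preventing overlapping windows from leaking
#'   across the split).
#' @param weight_decay decoupled weight decay on weight matrices
#'   (default 0.01).
#' @param class_weights optional per-class loss weights (default NULL:
#'   unweighted; imbalance is addressed by augmentation instead).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, learning_rate = 2e-5,
                         batch_size = 16L, seed = 1L,
                         split = c(train = 0.70, val = 0.15, test = 0.15),
                         split_mode = c("window_random", "grouped_by_source"),
                         weight_decay = 0.01, class_weights = NULL) {
  split <- unname(split)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 split = split,
                 split_mode = match.arg(split_mode),
                 weight_decay = weight_decay,
                 class_weights = class_weights),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parameter initialisation ----------------------------------------------

transformer_init <- function(cfg, vocab_size) {
  h <- cfg$hidden
  p <- list(
    tok_emb = nn_init_mat(vocab_size, h),
    pos_emb = nn_init_mat(cfg$max_len, h),
    ln_emb_g = rep(1, h), ln_emb_b = rep(0, h)
  )
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "Wq")]] <- nn_init_mat(h, h)
    p[[paste0(pre, "Wk")]] <- nn_init_mat(h, h)
    p[[paste0(pre, "Wv")]] <- nn_init_mat(h, h)
    p[[paste0(pre, "Wo")]] <- nn_init_mat(h, h)
    p[[paste0(pre, "bq")]] <- rep(0, h)
    p[[paste0(pre, "bk")]] <- rep(0, h)
    p[[paste0(pre, "bv")]] <- rep(0, h)
    p[[paste0(pre, "bo")]] <- rep(0, h)
    p[[paste0(pre, "ln1_g")]] <- rep(1, h)
    p[[paste0(pre, "ln1_b")]] <- rep(0, h)
    p[[paste0(pre, "W1")]] <- nn_init_mat(h, cfg$ffn_dim)
    p[[paste0(pre, "b1")]] <- rep(0, cfg$ffn_dim)
    p[[paste0(pre, "W2")]] <- nn_init_mat(cfg$ffn_dim, h)
    p[[paste0(pre, "b2")]] <- rep(0, h)
    p[[paste0(pre, "ln2_g")]] <- rep(1, h)
    p[[paste0(pre, "ln2_b")]] <- rep(0, h)
  }
  p$out_W <- nn_init_mat(h, cfg$n_classes)
  p$out_b <- rep(0, cfg$n_classes)
  p
}

#' Parameter count of a classifier configuration
#'
#' Closed-form total of embedding, encoder and head parameters.
#'
#' @param cfg a [model_config()].
#' @param vocab_size vocabulary size including special tokens.
#' @return Integer parameter count.
#' @export
n_parameters <- function(cfg, vocab_size) {
  h <- cfg$hidden; f <- cfg$ffn_dim
  emb <- vocab_size * h + cfg$max_len * h + 2 * h
  per_layer <- 4 * (h * h + h) +      # q, k, v, o projections
    2 * 2 * h +                       # two layer norms
    (h * f + f) + (f * h + h)         # feed-forward
  head <- h * cfg$n_classes + cfg$n_classes
  emb + cfg$layers * per_layer + head
}

# ---- attention -------------------------------------------------------------

# Q, K, V: (B*L, h) sample-major. Compiled inner loops; backward recomputes
# the attention softmax from Q and K instead of caching it.
attn_fwd <- function(Q, K, V, B, L, heads) {
  list(O = .attn_fwd_cpp(Q, K, V, B, L, heads))
}

attn_bwd <- function(dO, Q, K, V, B, L, heads) {
  .attn_bwd_cpp(dO, Q, K, V, B, L, heads)
}

# ---- forward / backward ----------------------------------------------------

# ids: (B, L) integer token ids (0-based). Returns logits and, when
# want_cache, everything backward needs.
transformer_fwd <- function(p, cfg, ids, want_cache = FALSE,
                            dropout_mask = NULL) {
  B <- nrow(ids); L <- ncol(ids)
  if (L > cfg$max_len) stop("sequence length ", L, " exceeds max_len")
  idx <- as.integer(t(ids)) + 1L            # sample-major rows
  X <- p$tok_emb[idx, , drop = FALSE] +
    p$pos_emb[rep(seq_len(L), B), , drop = FALSE]
  ln_emb <- nn_ln_fwd(X, p$ln_emb_g, p$ln_emb_b)
  X <- ln_emb$y
  caches <- if (want_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d.", l)
    Q <- nn_addb(X %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- nn_addb(X %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- nn_addb(X %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    at <- attn_fwd(Q, K, V, B, L, cfg$heads)
    A <- nn_addb(at$O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    ln1 <- nn_ln_fwd(X + A, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    X1 <- ln1$y
    Z1 <- nn_addb(X1 %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    G <- nn_gelu_fwd(Z1)
    F2 <- nn_addb(G$y %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    ln2 <- nn_ln_fwd(X1 + F2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    if (want_cache) {
      caches[[l]] <- list(X_in = X, Q = Q, K = K, V = V, at = at,
                          ln1 = ln1, X1 = X1, G = G, ln2 = ln2)
    }
    X <- ln2$y
  }
  cls_rows <- (seq_len(B) - 1L) * L + 1L
  cls <- X[cls_rows, , drop = FALSE]
  cls_d <- cls
  if (!is.null(dropout_mask)) cls_d <- cls * dropout_mask
  logits <- nn_addb(cls_d %*% p$out_W, p$out_b)
  if (!want_cache) return(list(logits = logits))
  list(logits = logits, caches = caches, ln_emb = ln_emb, idx = idx,
       cls = cls, cls_d = cls_d, cls_rows = cls_rows, B = B, L = L)
}

transformer_bwd <- function(p, cfg, fwd, dlogits, dropout_mask = NULL) {
  B <- fwd$B; L <- fwd$L
  g <- list()
  g$out_W <- crossprod(fwd$cls_d, dlogits)
  g$out_b <- colSums(dlogits)
  dcls <- tcrossprod(dlogits, p$out_W)
  if (!is.null(dropout_mask)) dcls <- dcls * dropout_mask
  dX <- matrix(0, B * L, cfg$hidden)
  dX[fwd$cls_rows, ] <- dcls
  for (l in rev(seq_len(cfg$layers))) {
    pre <- sprintf("L%d.", l)
    cache <- fwd$caches[[l]]
    ln2b <- nn_ln_bwd(dX, cache$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- ln2b$dg
    g[[paste0(pre, "ln2_b")]] <- ln2b$db
    dres2 <- ln2b$dx                       # grad wrt (X1 + F2)
    g[[paste0(pre, "W2")]] <- crossprod(cache$G$y, dres2)
    g[[paste0(pre, "b2")]] <- colSums(dres2)
    dGy <- tcrossprod(dres2, p[[paste0(pre, "W2")]])
    dZ1 <- nn_gelu_bwd(dGy, cache$G)
    g[[paste0(pre, "W1")]] <- crossprod(cache$X1, dZ1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dX1 <- dres2 + tcrossprod(dZ1, p[[paste0(pre, "W1")]])
    ln1b <- nn_ln_bwd(dX1, cache$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- ln1b$dg
    g[[paste0(pre, "ln1_b")]] <- ln1b$db
    dres1 <- ln1b$dx                       # grad wrt (X_in + A)
    g[[paste0(pre, "Wo")]] <- crossprod(cache$at$O, dres1)
    g[[paste0(pre, "bo")]] <- colSums(dres1)
    dO <- tcrossprod(dres1, p[[paste0(pre, "Wo")]])
    ab <- attn_bwd(dO, cache$Q, cache$K, cache$V, B, L, cfg$heads)
    g[[paste0(pre, "Wq")]] <- crossprod(cache$X_in, ab$dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cache$X_in, ab$dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cache$X_in, ab$dV)
    g[[paste0(pre, "bq")]] <- colSums(ab$dQ)
    g[[paste0(pre, "bk")]] <- colSums(ab$dK)
    g[[paste0(pre, "bv")]] <- colSums(ab$dV)
    dX <- dres1 +
      tcrossprod(ab$dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(ab$dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(ab$dV, p[[paste0(pre, "Wv")]])
  }
  lnb <- nn_ln_bwd(dX, fwd$ln_emb, p$ln_emb_g)
  g$ln_emb_g <- lnb$dg
  g$ln_emb_b <- lnb$db
  dE <- lnb$dx
  # token embedding: accumulate rows by id (sparse); position embedding:
  # accumulate rows by position
  uid <- sort(unique(fwd$idx))
  Gtok <- rowsum(dE, group = fwd$idx, reorder = TRUE)
  g$tok_emb <- list(idx = uid, G = Gtok)
  posg <- rowsum(dE, group = rep(seq_len(L), B), reorder = TRUE)
  g$pos_emb <- list(idx = seq_len(L), G = posg)
  g
}

# ---- dataset splitting -----------------------------------------------------

#' Split a window table into train / validation / test partitions
#'
#' Under `"window_random"`, windows are assigned at random stratified by
#' class so each partition's class proportions track the global ones.
#' Under `"grouped_by_source"`, whole sources (recordings) are assigned to
#' one partition, so overlapping windows from a single recording never
#' straddle the split. Deterministic given `cfg$seed`.
#'
#' @param windows a window table (needs `label` and, for grouped mode,
#'   `source` columns).
#' @param cfg a [train_config()].
#' @return List of integer row-index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(windows, cfg = train_config()) {
  n <- nrow(windows)
  stopifnot(n > 0L)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  frac <- cfg$split
  rng <- local_rng(cfg$seed)
  on.exit(rng(), add = TRUE)
  if (cfg$split_mode == "window_random") {
    for (cl in sort(unique(windows$label))) {
      idx <- which(windows$label == cl)
      m <- length(idx)
      if (m < 3L) {
        warning("class ", cl, " has fewer than 3 windows; kept whole in train")
        out$train <- c(out$train, idx)
        next
      }
      idx <- sample(idx)
      n_tr <- round(frac[1] * m)
      n_va <- round(frac[2] * m)
      keep_test <- frac[3] > 0
      n_tr <- min(max(n_tr, 1L), m - 1L - keep_test)
      n_va <- min(max(n_va, 1L), m - n_tr - keep_test)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
      if (n_tr + n_va < m) {
        rest <- idx[(n_tr + n_va + 1L):m]
        if (keep_test) out$test <- c(out$test, rest)
        else out$train <- c(out$train, rest)
      }
    }
  } else {
    src <- unique(windows$source)
    src <- sample(src)
    sizes <- vapply(src, function(s) sum(windows$source == s), integer(1))
    csum <- cumsum(sizes) / n
    part <- ifelse(csum <= frac[1], 1L,
                   ifelse(csum <= frac[1] + frac[2], 2L, 3L))
    # guarantee non-empty val (and test, when requested)
    if (!any(part == 2L)) part[max(which(part == 1L))] <- 2L
    if (frac[3] > 0 && !any(part == 3L)) part[length(part)] <- 3L
    out$train <- which(windows$source %in% src[part == 1L])
    out$val <- which(windows$source %in% src[part == 2L])
    out$test <- which(windows$source %in% src[part == 3L])
  }
  lapply(out, sort)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the transformer-encoder activity classifier
#'
#' Trains the sequence classifier on tokenized windows with AdamW and
#' cross-entropy, evaluating on the validation set after every epoch and
#' keeping the weights of the epoch with the best validation macro-F1
#' (falling back to final weights when no validation set is supplied).
#' Fully deterministic given `train_cfg$seed` on one device.
#'
#' @param tokens a [encode_windows()] result for the training windows.
#' @param labels integer class ids (1-based) for the training windows.
#' @param config a [model_config()].
#' @param train_cfg a [train_config()].
#' @param val_tokens,val_labels optional validation set used for model
#'   selection.
#' @param verbose print per-epoch progress.
#' @return A `pose_transformer` object with elements `params`, `config`,
#'   `train_cfg`, `history` (per-epoch data.frame), `best_epoch`,
#'   `vocab_size`, `n_parameters`.
#' @export
pose_transformer <- function(tokens, labels, config = model_config(),
                             train_cfg = train_config(),
                             val_tokens = NULL, val_labels = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(tokens, "token_sequences"))
  ids <- tokens$ids
  labels <- as.integer(labels)
  if (nrow(ids) == 0L) stop("empty training set")
  if (nrow(ids) != length(labels)) stop("tokens/labels length mismatch")
  rng <- local_rng(train_cfg$seed)
  on.exit(rng(), add = TRUE)

  p <- transformer_init(config, tokens$vocab_size)
  opt <- nn_adam_init(p)
  n <- nrow(ids)
  bs <- train_cfg$batch_size
  cw <- train_cfg$class_weights
  history <- data.frame()
  best <- list(f1 = -Inf, params = p, epoch = 0L)

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
    for (start in seq(1L, n, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      bi <- ids[take, , drop = FALSE]
      by <- labels[take]
      dm <- NULL
      if (config$dropout_head > 0) {
        keep <- matrix(runif(length(take) * config$hidden) > config$dropout_head,
                       length(take), config$hidden)
        dm <- keep / (1 - config$dropout_head)
      }
      fwd <- transformer_fwd(p, config, bi, want_cache = TRUE,
                             dropout_mask = dm)
      ce <- nn_xent_weighted(fwd$logits, by, cw)
      if (!is.finite(ce$loss)) {
        stop("non-finite loss at epoch ", epoch,
             " (batch starting at ", start, "); aborting")
      }
      grads <- transformer_bwd(p, config, fwd, ce$dlogits, dropout_mask = dm)
      step <- nn_adam_step(p, grads, opt, lr = train_cfg$learning_rate,
                           weight_decay = train_cfg$weight_decay)
      p <- step$params; opt <- step$state
      ep_loss <- ep_loss + ce$loss * length(take)
      ep_n <- ep_n + length(take)
      ep_correct <- ep_correct + sum(max.col(fwd$logits, "first") == by)
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                      train_acc = ep_correct / ep_n,
                      val_loss = NA_real_, val_macro_f1 = NA_real_,
                      val_acc = NA_real_)
    if (!is.null(val_tokens) && nrow(val_tokens$ids) > 0L) {
      vout <- transformer_fwd(p, config, val_tokens$ids)
      vce <- nn_xent(vout$logits, as.integer(val_labels))
      vpred <- max.col(vout$logits, "first")
      cm <- confusion(val_labels, vpred, config$n_classes)
      mr <- per_class_metrics(cm)
      row$val_loss <- vce$loss
      row$val_macro_f1 <- mr$macro["f1"]
      row$val_acc <- mean(vpred == val_labels)
      if (row$val_macro_f1 > best$f1) {
        best <- list(f1 = row$val_macro_f1, params = p, epoch = epoch)
      }
    }
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f acc %.3f val_f1 %s", epoch,
                      row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_macro_f1), "-",
                             sprintf("%.3f", row$val_macro_f1))))
    }
  }
  if (is.finite(best$f1)) { p <- best$params } else { best$epoch <- train_cfg$epochs }
  structure(list(params = p, config = config, train_cfg = train_cfg,
                 history = history, best_epoch = best$epoch,
                 vocab_size = tokens$vocab_size,
                 n_parameters = n_parameters(config, tokens$vocab_size)),
            class = "pose_transformer")
}

nn_xent_weighted <- function(logits, y, class_weights = NULL) {
  if (is.null(class_weights)) return(nn_xent(logits, y))
  p <- nn_softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  w <- class_weights[y]
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / sum(w)
  d <- p * w
  d[idx] <- d[idx] - w
  list(loss = loss, dlogits = d / sum(w), probs = p)
}

#' @export
print.pose_transformer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "pose_transformer (%s): %d layers, hidden %d, %d heads, %s parameters\n",
    cfg$preset, cfg$layers, cfg$hidden, cfg$heads,
    format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  trained %d epoch(s); best epoch %d\n",
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.pose_transformer <- function(object, ...) {
  cat("Transformer encoder activity classifier\n")
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f, train accuracy %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!all(is.na(h$val_macro_f1))) {
    cat(sprintf("  best validation macro-F1 %.3f (epoch %d)\n",
                max(h$val_macro_f1, na.rm = TRUE), object$best_epoch))
  }
  invisible(object)
}

#' Plot training history
#' @param x a fitted [pose_transformer()].
#' @param ... passed to [plot()].
#' @export
plot.pose_transformer <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch", ylab = "loss",
       main = "training history", ...)
  if (!all(is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, type = "b", col = 2)
    legend("topright", legend = c("train", "validation"), col = 1:2, lty = 1)
  }
  invisible(x)
}

#' Predict activity classes for tokenized windows
#'
#' Runs the encoder in evaluation mode (dropout disabled, so repeated calls
#' are bit-identical) and returns softmax class probabilities and argmax
#' labels (ties broken by lowest class id).
#'
#' @param object a fitted [pose_transformer()].
#' @param tokens a [encode_windows()] result.
#' @param batch_size evaluation batch size (affects memory only, never the
#'   predictions).
#' @param ... unused.
#' @return List with `prob` (matrix, rows summing to 1) and `class`
#'   (integer labels).
#' @export
predict.pose_transformer <- function(object, tokens, batch_size = 64L, ...) {
  stopifnot(inherits(tokens, "token_sequences"))
  ids <- tokens$ids
  if (ncol(ids) > object$config$max_len) {
    stop("sequence length exceeds max_len")
  }
  n <- nrow(ids)
  prob <- matrix(NA_real_, n, object$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    out <- transformer_fwd(object$params, object$config,
                           ids[take, , drop = FALSE])
    prob[take, ] <- nn_softmax(out$logits)
  }
  list(prob = prob, class = max.col(prob, "first"))
}
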