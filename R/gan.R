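#' Conditional tabular GAN configuration
#'
#' Architecture and optimisation settings for the tabular GAN that
#' synthesises minority-class feature rows. Generator and discriminator are
#' fully connected nets (two hidden layers by default, as is conventional
#' for conditional tabular GANs); the generator receives Gaussian noise
#' concatenated with the one-hot condition vector and emits, per continuous
#' column, a tanh `alpha` and a softmax over mixture modes, plus a softmax
#' over class labels; the discriminator scores the encoded row concatenated
#' with the condition. An auxiliary cross-entropy penalty pushes the
#' generated class one-hot to match the condition.
#'
#' @param generator_dims,discriminator_dims hidden layer widths
#'   (default `c(256, 256)`).
#' @param noise_dim dimension of the generator's Gaussian noise input
#'   (default 128).
#' @param epochs passes over the training rows (default 300).
#' @param batch_size minibatch size (default 64).
#' @param conditional_loss_weight weight of the auxiliary class penalty
#'   (default 1).
#' @param feature_match_weight weight of a feature-matching penalty: the
#'   squared distance between each generated row and its condition-matched
#'   real partner (default 0, off). Turning it on (weight about 1) anchors
#'   conditional generation when many classes have very few real rows, at
#'   some cost in within-class diversity.
#' @param learning_rate Adam learning rate for both nets (default 2e-4,
#'   betas 0.5/0.9).
#' @param vgm_modes maximum mixture modes per continuous column
#'   (default 10).
#' @param pac number of samples the discriminator judges jointly (packed
#'   discrimination, default 8; must divide `batch_size`). Packing lets
#'   the discriminator detect collapsed sample diversity, the standard
#'   counter to mode collapse in tabular GANs.
#' @param log_frequency sample training conditions from log frequencies
#'   instead of raw frequencies (default FALSE: raw frequencies).
#' @param seed integer seed.
#' @return A `gan_config` list.
#' @export
gan_config <- function(generator_dims = c(256L, 256L),
                       discriminator_dims = c(256L, 256L),
                       noise_dim = 128L, epochs = 300L, batch_size = 64L,
                       conditional_loss_weight = 1, feature_match_weight = 0,
                       learning_rate = 2e-4,
                       vgm_modes = 10L, pac = 8L, log_frequency = FALSE,
                       seed = 1L) {
  stopifnot(all(generator_dims > 0), all(discriminator_dims > 0),
            noise_dim > 0, batch_size > 0)
  if (batch_size %% pac != 0L) stop("batch_size must be a multiple of pac")
  structure(list(generator_dims = as.integer(generator_dims),
                 discriminator_dims = as.integer(discriminator_dims),
                 noise_dim = as.integer(noise_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 conditional_loss_weight = conditional_loss_weight,
                 feature_match_weight = feature_match_weight,
                 learning_rate = learning_rate,
                 vgm_modes = as.integer(vgm_modes),
                 pac = as.integer(pac),
                 log_frequency = isTRUE(log_frequency),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Sample conditioning classes by frequency (training-by-sampling)
#'
#' During GAN training the conditioning category of each generated row is
#' drawn from the empirical category frequencies of the discrete column
#' (here: the class label), so the generated label marginal matches the
#' real one. With `log_frequency = TRUE` the draw uses `log(1 + freq)`
#' instead, flattening the distribution towards rare classes.
#'
#' @param class_frequencies non-negative per-class counts or frequencies
#'   (names or positions give the class ids); at least one positive.
#' @param n number of draws.
#' @param log_frequency use log-frequency sampling.
#' @return Integer vector of class ids (uses the current RNG stream).
#' @export
sample_condition <- function(class_frequencies, n = 1L,
                             log_frequency = FALSE) {
  f <- as.numeric(class_frequencies)
  if (any(f < 0)) stop("negative class frequency")
  if (all(f == 0)) stop("all class frequencies are zero")
  if (log_frequency) f <- ifelse(f > 0, log1p(f), 0)
  ids <- if (!is.null(names(class_frequencies))) {
    as.integer(names(class_frequencies))
  } else {
    seq_along(f)
  }
  ids[sample.int(length(f), n, replace = TRUE, prob = f)]
}

# ---- row (en/de)coding -----------------------------------------------------

# Encode a feature matrix: per column (alpha, mode one-hot); returns the
# dense representation plus layout bookkeeping.
gan_encode_rows <- function(features, encoders) {
  n <- nrow(features)
  widths <- vapply(encoders, function(e) 1L + length(e$means), integer(1))
  total <- sum(widths)
  out <- matrix(0, n, total)
  off <- 0L
  for (j in seq_along(encoders)) {
    enc <- encoders[[j]]
    e <- vgm_encode(features[, j], enc)
    out[, off + 1L] <- e$alpha
    out[cbind(seq_len(n), off + 1L + e$mode)] <- 1
    off <- off + widths[j]
  }
  out
}

gan_decode_rows <- function(repr, encoders, widths) {
  n <- nrow(repr)
  out <- matrix(NA_real_, n, length(encoders))
  off <- 0L
  for (j in seq_along(encoders)) {
    enc <- encoders[[j]]
    k <- length(enc$means)
    alpha <- pmin(pmax(repr[, off + 1L], -1), 1)
    mode <- max.col(repr[, off + 1L + seq_len(k), drop = FALSE], "first")
    out[, j] <- vgm_decode(alpha, mode, enc)
    off <- off + widths[j]
  }
  out
}

# pack pac consecutive rows into one wide row (and invert, for gradients)
pack_rows <- function(m, pac) {
  if (pac == 1L) return(m)
  matrix(t(m), nrow = nrow(m) %/% pac, byrow = TRUE)
}
unpack_rows <- function(m, pac, row_dim) {
  if (pac == 1L) return(m)
  matrix(t(m), ncol = row_dim, byrow = TRUE)
}

# ---- the GAN ---------------------------------------------------------------

#' Fit the conditional tabular GAN on labeled feature rows
#'
#' Continuous columns are normalised with per-column Gaussian-mixture
#' encoders ([fit_vgm()]); the class label is the single discrete column
#' and doubles as the condition. Training alternates one discriminator and
#' one generator step per minibatch: the condition is drawn by
#' training-by-sampling ([sample_condition()]), real rows are resampled to
#' match the drawn conditions, and the generator is additionally penalised
#' (cross-entropy) when its generated class one-hot departs from the
#' condition. Deterministic given `config$seed`; aborts if losses become
#' non-finite.
#'
#' @param features numeric matrix or window table (continuous columns
#'   only).
#' @param labels integer class ids, one per row; every class to be
#'   generated must be present.
#' @param config a [gan_config()].
#' @param n_classes total number of classes (default: max label).
#' @param verbose print progress every 50 epochs.
#' @return A `tabular_gan` object; use [simulate.tabular_gan()] or
#'   [generate()] to draw synthetic rows.
#' @export
tabular_gan <- function(features, labels, config = gan_config(),
                        n_classes = NULL, verbose = FALSE) {
  if (is.data.frame(features)) features <- window_features(features)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), nrow(features) > 0L)
  n_classes <- as.integer(n_classes %||% max(labels))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  encoders <- lapply(seq_len(ncol(features)),
                     function(j) fit_vgm(features[, j], k = config$vgm_modes))
  widths <- vapply(encoders, function(e) 1L + length(e$means), integer(1))
  repr <- gan_encode_rows(features, encoders)
  data_dim <- ncol(repr)
  class_onehot <- matrix(0, nrow(repr), n_classes)
  class_onehot[cbind(seq_len(nrow(repr)), labels)] <- 1

  freq <- tabulate(labels, n_classes)
  by_class <- split(seq_along(labels), labels)

  g_out_dim <- data_dim + n_classes
  pac <- config$pac
  row_dim <- data_dim + n_classes + n_classes   # repr + class one-hot + cond
  gdims <- c(config$noise_dim + n_classes, config$generator_dims, g_out_dim)
  ddims <- c(pac * row_dim, config$discriminator_dims, 1L)
  gp <- nn_mlp_init(gdims, "g.")
  dp <- nn_mlp_init(ddims, "d.")
  g_opt <- nn_adam_init(gp)
  d_opt <- nn_adam_init(dp)
  gl <- length(gdims) - 1L
  dl <- length(ddims) - 1L
  lr <- config$learning_rate
  bs <- config$batch_size
  n <- nrow(repr)
  iters <- max(1L, ceiling(n / bs))
  history <- data.frame()

  # split a raw generator output into activated heads + caches
  activate <- function(raw) {
    act <- matrix(0, nrow(raw), g_out_dim)
    sm_caches <- list()
    off <- 0L
    for (j in seq_along(widths)) {
      act[, off + 1L] <- tanh(raw[, off + 1L])
      k <- widths[j] - 1L
      blk <- off + 1L + seq_len(k)
      P <- nn_softmax(raw[, blk, drop = FALSE])
      act[, blk] <- P
      sm_caches[[j]] <- P
      off <- off + widths[j]
    }
    cls_blk <- data_dim + seq_len(n_classes)
    Pc <- nn_softmax(raw[, cls_blk, drop = FALSE])
    act[, cls_blk] <- Pc
    list(act = act, sm = sm_caches, Pc = Pc, cls_blk = cls_blk)
  }
  # gradient wrt raw outputs given gradient wrt activated heads
  activate_bwd <- function(dact, raw, hc) {
    draw <- matrix(0, nrow(raw), g_out_dim)
    off <- 0L
    for (j in seq_along(widths)) {
      a <- tanh(raw[, off + 1L])
      draw[, off + 1L] <- dact[, off + 1L] * (1 - a^2)
      k <- widths[j] - 1L
      blk <- off + 1L + seq_len(k)
      P <- hc$sm[[j]]
      dP <- dact[, blk, drop = FALSE]
      draw[, blk] <- (dP - rowSums(dP * P)) * P
      off <- off + widths[j]
    }
    P <- hc$Pc
    dP <- dact[, hc$cls_blk, drop = FALSE]
    draw[, hc$cls_blk] <- (dP - rowSums(dP * P)) * P
    draw
  }

  for (epoch in seq_len(config$epochs)) {
    d_loss_ep <- 0; g_loss_ep <- 0
    for (it in seq_len(iters)) {
      cond_cls <- sample_condition(freq, bs, config$log_frequency)
      cond <- matrix(0, bs, n_classes)
      cond[cbind(seq_len(bs), cond_cls)] <- 1
      real_idx <- vapply(cond_cls, function(cl) {
        pool <- by_class[[as.character(cl)]]
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      real_in <- pack_rows(cbind(repr[real_idx, , drop = FALSE],
                                 class_onehot[real_idx, , drop = FALSE],
                                 cond), pac)

      z <- matrix(rnorm(bs * config$noise_dim), bs)
      gf <- nn_mlp_fwd(cbind(z, cond), gp, "g.", gl)
      hc <- activate(gf$out)
      fake_in <- pack_rows(cbind(hc$act, cond), pac)

      # --- discriminator step
      df_r <- nn_mlp_fwd(real_in, dp, "d.", dl, act = "leaky")
      df_f <- nn_mlp_fwd(fake_in, dp, "d.", dl, act = "leaky")
      br <- nn_bce(df_r$out, 1)
      bf <- nn_bce(df_f$out, 0)
      gr <- nn_mlp_bwd(br$dlogits, df_r, dp, "d.", dl, act = "leaky")$grads
      gfk <- nn_mlp_bwd(bf$dlogits, df_f, dp, "d.", dl, act = "leaky")$grads
      dg <- Map(`+`, gr, gfk[names(gr)])
      st <- nn_adam_step(dp, dg, d_opt, lr, beta1 = 0.5, beta2 = 0.9)
      dp <- st$params; d_opt <- st$state
      d_loss <- br$loss + bf$loss

      # --- generator step (non-saturating + conditional penalty)
      df_f2 <- nn_mlp_fwd(fake_in, dp, "d.", dl, act = "leaky")
      bg <- nn_bce(df_f2$out, 1)
      db <- nn_mlp_bwd(bg$dlogits, df_f2, dp, "d.", dl, act = "leaky")
      dact <- unpack_rows(db$d_input, pac, row_dim)[, seq_len(g_out_dim),
                                                    drop = FALSE]
      draw <- activate_bwd(dact, gf$out, hc)
      # auxiliary class penalty: CE(class softmax, condition)
      ce_loss <- -mean(log(pmax(hc$Pc[cbind(seq_len(bs), cond_cls)], 1e-12)))
      dce <- hc$Pc
      dce[cbind(seq_len(bs), cond_cls)] <- dce[cbind(seq_len(bs), cond_cls)] - 1
      draw[, hc$cls_blk] <- draw[, hc$cls_blk] +
        config$conditional_loss_weight * dce / bs
      # feature matching: pull each generated row toward its
      # condition-matched real partner (conditional moment constraint;
      # the adversarial term supplies within-class variety)
      if (config$feature_match_weight > 0) {
        fm_diff <- hc$act[, seq_len(data_dim), drop = FALSE] -
          repr[real_idx, , drop = FALSE]
        dact_fm <- cbind(2 * fm_diff / bs, matrix(0, bs, n_classes))
        draw <- draw + config$feature_match_weight *
          activate_bwd(dact_fm, gf$out, hc)
      }
      gb <- nn_mlp_bwd(draw, gf, gp, "g.", gl)
      st <- nn_adam_step(gp, gb$grads, g_opt, lr, beta1 = 0.5, beta2 = 0.9)
      gp <- st$params; g_opt <- st$state
      g_loss <- bg$loss + config$conditional_loss_weight * ce_loss

      if (!is.finite(d_loss) || !is.finite(g_loss)) {
        stop("GAN diverged (non-finite loss) at epoch ", epoch)
      }
      d_loss_ep <- d_loss_ep + d_loss
      g_loss_ep <- g_loss_ep + g_loss
    }
    history <- rbind(history, data.frame(
      epoch = epoch, d_loss = d_loss_ep / iters, g_loss = g_loss_ep / iters))
    if (verbose && epoch %% 50L == 0L) {
      message(sprintf("gan epoch %d: d %.3f g %.3f", epoch,
                      d_loss_ep / iters, g_loss_ep / iters))
    }
  }

  structure(list(g_params = gp, g_layers = gl, encoders = encoders,
                 widths = widths, data_dim = data_dim,
                 n_classes = n_classes, freq = freq, config = config,
                 feature_names = colnames(features) %||%
                   feature_names(ncol(features)),
                 history = history),
            class = "tabular_gan")
}

#' @export
print.tabular_gan <- function(x, ...) {
  cat(sprintf(
    "tabular_gan: %d continuous columns (encoded dim %d), %d classes\n",
    length(x$encoders), x$data_dim, x$n_classes))
  cat(sprintf("  trained %d epochs; final d/g loss %.3f / %.3f\n",
              nrow(x$history), x$history$d_loss[nrow(x$history)],
              x$history$g_loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.tabular_gan <- function(object, ...) {
  print(object)
  modes <- vapply(object$encoders, function(e) length(e$means), integer(1))
  cat(sprintf("  mixture modes per column: min %d, median %g, max %d\n",
              min(modes), stats::median(modes), max(modes)))
  invisible(object)
}

#' Draw synthetic rows from a fitted tabular GAN
#'
#' `simulate()` is the S3 entry point; [generate()] is a thin wrapper with
#' the (class, n) argument order. The requested class is fed to the
#' generator as the condition vector and enforced on the output label at
#' decode time, so conditional integrity is exact by construction. Mixture
#' modes are sampled from the generated softmax; alphas pass through tanh
#' and decode via the column encoders.
#'
#' @param object a fitted [tabular_gan()].
#' @param nsim number of rows.
#' @param seed integer seed (required for reproducibility; default 1).
#' @param class class id to condition on; `NULL` samples classes from the
#'   training frequencies.
#' @param ... unused.
#' @return data.frame: `label` plus the feature columns.
#' @export
simulate.tabular_gan <- function(object, nsim = 1L, seed = 1L,
                                 class = NULL, ...) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- as.integer(nsim)
  p <- length(object$encoders)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = p))
    names(out) <- object$feature_names
    return(cbind(data.frame(label = integer(0)), out))
  }
  if (is.null(class)) {
    cls <- sample_condition(object$freq, n, object$config$log_frequency)
  } else {
    class <- as.integer(class)
    if (class < 1L || class > object$n_classes) {
      stop("unknown class ", class)
    }
    cls <- rep(class, n)
  }
  cond <- matrix(0, n, object$n_classes)
  cond[cbind(seq_len(n), cls)] <- 1
  z <- matrix(rnorm(n * object$config$noise_dim), n)
  raw <- nn_mlp_fwd(cbind(z, cond), object$g_params, "g.", object$g_layers)$out
  # activate + sample modes
  repr <- matrix(0, n, object$data_dim)
  off <- 0L
  for (j in seq_len(p)) {
    k <- object$widths[j] - 1L
    repr[, off + 1L] <- tanh(raw[, off + 1L])
    P <- nn_softmax(raw[, off + 1L + seq_len(k), drop = FALSE])
    u <- runif(n)
    cum <- t(apply(P, 1L, cumsum))
    mode <- max.col(cum >= u, ties.method = "first")
    repr[cbind(seq_len(n), off + 1L + mode)] <- 1
    off <- off + object$widths[j]
  }
  feats <- gan_decode_rows(repr, object$encoders, object$widths)
  colnames(feats) <- object$feature_names
  cbind(data.frame(label = cls), as.data.frame(feats))
}

#' @rdname simulate.tabular_gan
#' @param model a fitted [tabular_gan()].
#' @param n number of rows (>= 0).
#' @export
generate <- function(model, class, n, seed = 1L) {
  stopifnot(inherits(model, "tabular_gan"), n >= 0)
  simulate(model, nsim = n, seed = seed, class = class)
}

# ---- augmentation planning -------------------------------------------------

#' Plan per-class synthetic row counts
#'
#' Two strategies. `"published"` reproduces the published augmentation of
#' the UP-Fall window table: the seven minority classes (rows 1-6 and 10 of
#' the class table) receive their printed fake counts (17,267; 6,731;
#' 7,533; 16,759; 7,747; 14,784; 13,244 — an overall dataset growth of
#' about 40%); majority classes receive none. `"target_share"` raises every
#' class whose share of the final dataset would fall below `target` up to
#' that share (solved jointly by fixed-point iteration, since adding rows
#' enlarges the total); classes already at or above the target get zero.
#'
#' @param class_counts named or positional integer vector of observed
#'   per-class row counts (length 12 for the published strategy).
#' @param strategy `"published"` or `"target_share"`.
#' @param target desired final share per minority class (e.g. 0.05), for
#'   `"target_share"`.
#' @return An `augmentation_plan`: integer vector of per-class fake counts.
#' @export
build_plan <- function(class_counts,
                       strategy = c("published", "target_share"),
                       target = NULL) {
  strategy <- match.arg(strategy)
  counts <- as.integer(class_counts)
  if (any(counts < 0)) stop("negative class counts")
  if (strategy == "published") {
    fake <- upfall_tables()$windows$n_fake
    if (length(counts) != length(fake)) {
      stop("published plan needs all ", length(fake), " classes")
    }
    plan <- fake
  } else {
    if (is.null(target) || target <= 0 || target >= 1) {
      stop("target_share needs a target share in (0, 1)")
    }
    # only classes below target in the original mix are raised; classes with
    # no real rows cannot be augmented meaningfully and are skipped
    minority <- counts / sum(counts) < target & counts > 0L
    if (sum(minority) * target >= 1) {
      stop("target share ", target, " is infeasible for ", sum(minority),
           " minority classes (shares would exceed 100%)")
    }
    plan <- rep(0L, length(counts))
    converged <- FALSE
    for (i in 1:200) {
      total <- sum(counts) + sum(plan)
      want <- pmax(0, ceiling(target * total - counts))
      want[!minority] <- 0L
      if (all(want == plan)) { converged <- TRUE; break }
      plan <- as.integer(want)
    }
    if (!converged) stop("target share ", target, " did not converge")
  }
  structure(setNames(as.integer(plan),
                     names(class_counts) %||% seq_along(counts)),
            class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("augmentation plan (synthetic rows per class):\n")
  print(unclass(x))
  cat(sprintf("  total synthetic rows: %d\n", sum(x)))
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

#' Real-versus-synthetic distribution diagnostics
#'
#' Per feature: mean and standard deviation of the real and the synthetic
#' rows, and the maximum absolute gap between their empirical CDFs
#' (two-sample Kolmogorov-Smirnov statistic). Perfectly matching synthetic
#' data puts every point on the mean/SD diagonal with CDF gap 0.
#'
#' @param real,fake matrices or data.frames with identical feature columns
#'   (label columns are ignored).
#' @return A `gan_diagnostics` data.frame: `feature`, `mean_real`,
#'   `mean_fake`, `sd_real`, `sd_fake`, `cdf_gap`.
#' @export
gan_diagnostics <- function(real, fake) {
  get_mat <- function(x) {
    if (is.data.frame(x)) {
      fcols <- grep("^f[0-9]+$", names(x), value = TRUE)
      if (length(fcols)) x <- x[, fcols, drop = FALSE]
      else x <- x[, setdiff(names(x), "label"), drop = FALSE]
    }
    as.matrix(x)
  }
  r <- get_mat(real); f <- get_mat(fake)
  if (nrow(r) == 0L || nrow(f) == 0L) stop("empty input")
  if (ncol(r) != ncol(f) ||
      !identical(colnames(r), colnames(f))) {
    stop("real and synthetic tables must share the same feature columns")
  }
  ks_gap <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  out <- data.frame(
    feature = colnames(r) %||% feature_names(ncol(r)),
    mean_real = colMeans(r), mean_fake = colMeans(f),
    sd_real = apply(r, 2L, sd), sd_fake = apply(f, 2L, sd),
    cdf_gap = vapply(seq_len(ncol(r)),
                     function(j) ks_gap(r[, j], f[, j]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("gan_diagnostics", "data.frame")
  out
}

#' @export
plot.gan_diagnostics <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op), add = TRUE)
  lim <- range(c(x$mean_real, x$mean_fake))
  plot(x$mean_real, x$mean_fake, xlab = "real mean", ylab = "synthetic mean",
       xlim = lim, ylim = lim, main = "per-feature mean", ...)
  abline(0, 1, col = "grey")
  lim <- range(c(x$sd_real, x$sd_fake))
  plot(x$sd_real, x$sd_fake, xlab = "real SD", ylab = "synthetic SD",
       xlim = lim, ylim = lim, main = "per-feature SD", ...)
  abline(0, 1, col = "grey")
  invisible(x)
}
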