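# Minimal neural-network primitives: forward/backward pairs for the layers
# used by the transformer encoder and the GAN nets, plus AdamW. Everything
# operates on plain matrices so BLAS does the heavy lifting; gradients are
# hand-derived. Internal only.

nn_init_mat <- function(nr, nc, sd = 0.02) {
  matrix(rnorm(nr * nc, 0, sd), nr, nc)
}

# --- layer norm (per row, over columns) -------------------------------------

nn_ln_fwd <- function(x, g, b, eps = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv_sd = inv_sd)
}

nn_ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# --- activations ------------------------------------------------------------

nn_gelu_fwd <- function(x) {
  t <- tanh(0.7978845608028654 * x * (1 + 0.044715 * x * x))
  list(y = 0.5 * x * (1 + t), t = t, x = x)
}

nn_gelu_bwd <- function(dy, cache) {
  x <- cache$x; t <- cache$t
  du <- 0.7978845608028654 + 0.10703222440890037 * x * x
  dy * (0.5 * (1 + t) + 0.5 * (x * (1 - t * t)) * du)
}

# bias add without sweep()'s aperm overhead
nn_addb <- function(m, b) m + rep(b, each = nrow(m))

nn_relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache$mask

nn_leaky_relu_fwd <- function(x, slope = 0.2) {
  list(y = ifelse(x > 0, x, slope * x), mask = x > 0, slope = slope)
}
nn_leaky_relu_bwd <- function(dy, cache) {
  dy * ifelse(cache$mask, 1, cache$slope)
}

# --- softmax / losses -------------------------------------------------------

nn_softmax <- function(z) {
  zmax <- z[cbind(seq_len(nrow(z)), max.col(z, "first"))]
  e <- exp(z - zmax)
  e / rowSums(e)
}

# mean cross-entropy over rows; y is an integer class vector (1-based)
nn_xent <- function(logits, y) {
  p <- nn_softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# binary cross-entropy from logits against constant target (0 or 1)
nn_bce <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  loss <- -mean(ifelse(target == 1, log(pmax(p, 1e-12)),
                       log(pmax(1 - p, 1e-12))))
  dlogits <- (p - target) / length(logits)
  list(loss = loss, dlogits = dlogits, p = p)
}

# --- AdamW ------------------------------------------------------------------

nn_adam_init <- function(params) {
  zero <- function(p) { p[] <- 0; p }
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

# Decoupled weight decay applied to 2-D weight matrices only (not biases,
# layer-norm parameters or embeddings). grads may contain a sparse embedding
# gradient of the form list(idx = rows, G = matrix); only those rows are
# updated for that parameter (lazy update).
nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.list(g)) {                      # sparse rows
      idx <- g$idx
      gm <- g$G
      m <- state$m[[nm]][idx, , drop = FALSE] * beta1 + (1 - beta1) * gm
      v <- state$v[[nm]][idx, , drop = FALSE] * beta2 + (1 - beta2) * gm^2
      state$m[[nm]][idx, ] <- m
      state$v[[nm]][idx, ] <- v
      params[[nm]][idx, ] <- params[[nm]][idx, , drop = FALSE] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    } else {
      m <- state$m[[nm]] * beta1 + (1 - beta1) * g
      v <- state$v[[nm]] * beta2 + (1 - beta2) * g^2
      state$m[[nm]] <- m
      state$v[[nm]] <- v
      upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      if (weight_decay > 0 && is.matrix(params[[nm]]) &&
          !grepl("(_g|_b|emb)$", nm)) {
        upd <- upd + lr * weight_decay * params[[nm]]
      }
      params[[nm]] <- params[[nm]] - upd
    }
  }
  list(params = params, state = state)
}

# --- simple MLP (used by the GAN nets) --------------------------------------

# dims: c(in, hidden..., out); act: "relu" or "leaky"; linear output layer
nn_mlp_init <- function(dims, prefix) {
  p <- list()
  for (i in seq_len(length(dims) - 1L)) {
    fan_in <- dims[i]
    p[[paste0(prefix, "W", i)]] <- nn_init_mat(dims[i], dims[i + 1L],
                                               sd = sqrt(2 / fan_in))
    p[[paste0(prefix, "b", i)]] <- rep(0, dims[i + 1L])
  }
  p
}

nn_mlp_fwd <- function(x, p, prefix, n_layers, act = "relu") {
  caches <- vector("list", n_layers)
  h <- x
  for (i in seq_len(n_layers)) {
    z <- h %*% p[[paste0(prefix, "W", i)]]
    z <- nn_addb(z, p[[paste0(prefix, "b", i)]])
    if (i < n_layers) {
      a <- if (act == "leaky") nn_leaky_relu_fwd(z) else nn_relu_fwd(z)
      caches[[i]] <- list(input = h, act = a)
      h <- a$y
    } else {
      caches[[i]] <- list(input = h)
      h <- z
    }
  }
  list(out = h, caches = caches)
}

nn_mlp_bwd <- function(dout, fwd, p, prefix, n_layers, act = "relu") {
  grads <- list()
  d <- dout
  for (i in rev(seq_len(n_layers))) {
    cache <- fwd$caches[[i]]
    if (i < n_layers) {
      d <- if (act == "leaky") nn_leaky_relu_bwd(d, cache$act)
           else nn_relu_bwd(d, cache$act)
    }
    grads[[paste0(prefix, "W", i)]] <- crossprod(cache$input, d)
    grads[[paste0(prefix, "b", i)]] <- colSums(d)
    if (i > 1L) d <- tcrossprod(d, p[[paste0(prefix, "W", i)]])
  }
  d_in <- tcrossprod(d, p[[paste0(prefix, "W1")]])
  list(grads = grads, d_input = d_in)
}
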