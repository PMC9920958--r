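#' Fit a mode-specific (variational Gaussian mixture) column encoder
#'
#' Tabular GANs normalise each continuous column with a Gaussian mixture:
#' a value is expressed as the mode it belongs to (one-hot) plus a scalar
#' `alpha` giving its position within that mode, `alpha = (x - mu) / (4 sd)`
#' clipped to `[-1, 1]`. The mixture is fitted by variational Bayesian
#' inference with a Dirichlet prior over weights, which shrinks superfluous
#' components; components whose posterior weight falls below `prune` are
#' discarded and the weights renormalised.
#'
#' A constant column degenerates to a single mode whose standard deviation
#' is floored at 1e-6 of the column range (or 1e-6 absolute when the range
#' is zero), so encoding and decoding still round-trip.
#'
#' @param x numeric vector (one continuous column).
#' @param k maximum number of mixture modes (default 10).
#' @param prune weight threshold below which modes are dropped
#'   (default 1e-3).
#' @param max_iter,tol variational-EM iteration controls.
#' @param merge_sd components whose means lie within `merge_sd` standard
#'   deviations of each other after fitting are merged into one mode
#'   (moment-matched); set 0 to disable.
#' @return A `vgm_encoder`: `means`, `sds`, `weights` (summing to 1) of the
#'   retained modes.
#' @export
fit_vgm <- function(x, k = 10L, prune = 1e-3, max_iter = 100L, tol = 1e-6,
                    merge_sd = 2) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("non-finite values in column")
  n <- length(x)
  if (n == 0L) stop("empty column")
  rng_x <- diff(range(x))
  sd_floor <- if (rng_x > 0) 1e-6 * rng_x else 1e-6
  if (rng_x == 0 || length(unique(x)) == 1L) {
    return(structure(list(means = x[1L], sds = sd_floor, weights = 1),
                     class = "vgm_encoder"))
  }
  k <- min(as.integer(k), length(unique(x)))

  # variational Bayesian GMM, 1-D, Normal-Gamma + Dirichlet priors
  alpha0 <- 1 / k
  beta0 <- 1
  m0 <- mean(x)
  a0 <- 1
  b0 <- var(x)
  # init responsibilities from quantile-based hard assignment
  centers <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  assign0 <- apply(abs(outer(x, centers, `-`)), 1L, which.min)
  R <- matrix(1e-10, n, k)
  R[cbind(seq_len(n), assign0)] <- 1
  R <- R / rowSums(R)

  prev_bound <- -Inf
  for (iter in seq_len(max_iter)) {
    Nk <- colSums(R) + 1e-10
    xbar <- colSums(R * x) / Nk
    Sk <- colSums(R * (outer(x, xbar, `-`))^2) / Nk
    # posterior parameters
    alpha_k <- alpha0 + Nk
    beta_k <- beta0 + Nk
    m_k <- (beta0 * m0 + Nk * xbar) / beta_k
    a_k <- a0 + Nk / 2
    b_k <- b0 + 0.5 * (Nk * Sk + beta0 * Nk * (xbar - m0)^2 / beta_k)
    # expectations for the E-step
    ln_pi <- digamma(alpha_k) - digamma(sum(alpha_k))
    ln_lam <- digamma(a_k) - log(b_k)
    E_lam <- a_k / b_k
    quad <- outer(x, m_k, `-`)^2
    log_rho <- matrix(ln_pi, n, k, byrow = TRUE) +
      0.5 * matrix(ln_lam, n, k, byrow = TRUE) -
      0.5 * (sweep(quad, 2, E_lam, `*`) +
               matrix(1 / beta_k, n, k, byrow = TRUE))
    log_rho <- log_rho - apply(log_rho, 1L, max)
    R <- exp(log_rho)
    R <- R / rowSums(R)
    bound <- sum(log(rowSums(exp(log_rho))))  # cheap convergence proxy
    if (is.finite(prev_bound) && abs(bound - prev_bound) < tol * n) break
    prev_bound <- bound
  }
  w <- (alpha_k - alpha0) / sum(alpha_k - alpha0)
  keep <- which(w > prune)
  if (length(keep) == 0L) keep <- which.max(w)
  means <- m_k[keep]
  sds <- pmax(sqrt(b_k[keep] / a_k[keep]), sd_floor)
  weights <- w[keep] / sum(w[keep])
  # Merge components whose means overlap within one standard deviation:
  # variational fits tile a broad unimodal density with several overlapping
  # Gaussians, and a single merged mode both recovers the density's
  # parameters and keeps the encoded representation compact. Genuinely
  # separated modes (means further apart than their spreads) are untouched.
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  repeat {
    if (length(means) == 1L) break
    gap <- diff(means) < merge_sd * pmax(head(sds, -1), tail(sds, -1))
    if (!any(gap)) break
    j <- which(gap)[1L]
    w2 <- weights[j] + weights[j + 1L]
    mu <- (weights[j] * means[j] + weights[j + 1L] * means[j + 1L]) / w2
    m2 <- (weights[j] * (sds[j]^2 + means[j]^2) +
             weights[j + 1L] * (sds[j + 1L]^2 + means[j + 1L]^2)) / w2
    means <- c(means[seq_len(j - 1L)], mu, means[-seq_len(j + 1L)])
    sds <- c(sds[seq_len(j - 1L)], sqrt(pmax(m2 - mu^2, sd_floor^2)),
             sds[-seq_len(j + 1L)])
    weights <- c(weights[seq_len(j - 1L)], w2, weights[-seq_len(j + 1L)])
  }
  structure(list(means = means, sds = sds, weights = weights),
            class = "vgm_encoder")
}

#' @export
print.vgm_encoder <- function(x, ...) {
  cat(sprintf("vgm_encoder: %d mode(s)\n", length(x$means)))
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights))
  invisible(x)
}

#' Encode values with a fitted mode-specific encoder
#'
#' For each value a mode is sampled proportional to its posterior
#' responsibility (uses the current RNG stream; seed at the caller), and
#' the within-mode position `alpha = (x - mu)/(4 sd)` is clipped to
#' `[-1, 1]`.
#'
#' @param x numeric vector.
#' @param enc a [fit_vgm()] encoder.
#' @return List with `alpha` (numeric) and `mode` (integer, 1-based).
#' @export
vgm_encode <- function(x, enc) {
  stopifnot(inherits(enc, "vgm_encoder"))
  k <- length(enc$means)
  if (k == 1L) {
    mode <- rep(1L, length(x))
  } else {
    dens <- vapply(seq_len(k), function(j) {
      enc$weights[j] * dnorm(x, enc$means[j], enc$sds[j])
    }, numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    rs <- rowSums(dens)
    flat <- rs <= 0 | !is.finite(rs)
    if (any(flat)) {
      # far outside every mode: fall back to nearest mean
      nearest <- apply(abs(outer(x[flat], enc$means, `-`)), 1L, which.min)
      dens[flat, ] <- 0
      dens[cbind(which(flat), nearest)] <- 1
      rs[flat] <- 1
    }
    u <- runif(length(x))
    cum <- t(apply(dens / rs, 1L, cumsum))
    mode <- max.col(cum >= u, ties.method = "first")
  }
  alpha <- (x - enc$means[mode]) / (4 * enc$sds[mode])
  list(alpha = pmin(pmax(alpha, -1), 1), mode = as.integer(mode))
}

#' Decode (alpha, mode) pairs back to the original scale
#'
#' Exact inverse of [vgm_encode()] whenever alpha was not clipped:
#' `x = alpha * 4 sd_mode + mu_mode`.
#'
#' @param alpha numeric vector in `[-1, 1]`.
#' @param mode integer mode indices.
#' @param enc a [fit_vgm()] encoder.
#' @return Numeric vector.
#' @export
vgm_decode <- function(alpha, mode, enc) {
  stopifnot(inherits(enc, "vgm_encoder"))
  alpha * 4 * enc$sds[mode] + enc$means[mode]
}
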