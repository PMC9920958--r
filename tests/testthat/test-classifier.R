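# shared tiny fixture: two well-separated synthetic classes, tokenized
local_toy <- local({
  set.seed(41)
  n <- 100
  f1 <- matrix(rnorm(n / 2 * 153, 100, 5), n / 2)
  f2 <- matrix(rnorm(n / 2 * 153, 300, 5), n / 2)
  feats <- rbind(f1, f2)
  labels <- rep(1:2, each = n / 2)
  scaler <- fit_scaler(feats, vocab_numeric = 64)
  list(tokens = encode_windows(feats, scaler), labels = labels)
})

test_that("configs validate their invariants and count parameters in closed form", {
  expect_error(model_config(hidden = 65, heads = 4), "divisible")
  expect_error(model_config(n_classes = 1), "at least 2")
  expect_error(train_config(split = c(0.8, 0.1, 0.2)), "sum to 1")

  cfg <- model_config("tiny")
  expect_equal(cfg$layers, 2L)
  expect_equal(cfg$hidden, 64L)
  # analytic parameter count: embeddings + per-layer blocks + head
  v <- 100L
  expect_equal(
    n_parameters(cfg, v),
    (v * 64 + 512 * 64 + 2 * 64) +
      2 * (4 * (64 * 64 + 64) + 2 * 2 * 64 + (64 * 128 + 128) + (128 * 64 + 64)) +
      (64 * 12 + 12))
  # the full-size preset is in the ~110M-parameter regime
  expect_equal(n_parameters(model_config("base"), 30004L) / 1e6, 110,
               tolerance = 0.05)
})

test_that("an initialized model matches the analytic parameter count and shapes", {
  cfg <- model_config("tiny", n_classes = 5)
  ns <- asNamespace("skelseq")
  p <- ns$transformer_init(cfg, 80L)
  total <- sum(vapply(p, length, numeric(1)))
  expect_equal(total, n_parameters(cfg, 80L))
  out <- ns$transformer_fwd(p, cfg, matrix(0:9, 2, 5))
  expect_equal(dim(out$logits), c(2L, 5L))
})

test_that("stratified random splits are deterministic, disjoint and proportional", {
  w <- make_windows(n_per_class = 20L, classes = 1:4)
  cfg <- train_config(seed = 99)
  s1 <- split_dataset(w, cfg)
  s2 <- split_dataset(w, cfg)
  expect_identical(s1, s2)
  expect_equal(sort(unname(unlist(s1))), seq_len(nrow(w)))
  expect_equal(lengths(s1), c(train = 56L, val = 12L, test = 12L))
  # per-class proportions in train within one window of the global share
  for (cl in 1:4) {
    expect_equal(sum(w$label[s1$train] == cl), 0.7 * 20, tolerance = 0.05)
  }
  # tiny classes stay whole in train, with a warning
  w_small <- rbind(w, w[w$label == 1, ][1:2, ])
  w_small$label[81:82] <- 5L
  expect_warning(s3 <- split_dataset(w_small, cfg), "fewer than 3")
  expect_true(all(which(w_small$label == 5L) %in% s3$train))
})

test_that("grouped splits never let a source straddle partitions", {
  w <- make_windows(n_per_class = 20L, classes = 1:3)
  cfg <- train_config(seed = 7, split_mode = "grouped_by_source")
  s <- split_dataset(w, cfg)
  for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
    shared <- intersect(unique(w$source[s[[pair[1]]]]),
                        unique(w$source[s[[pair[2]]]]))
    expect_length(shared, 0)
  }
  expect_equal(sort(unname(unlist(s))), seq_len(nrow(w)))
})

test_that("an untrained model starts near the uniform cross-entropy ln(12)", {
  set.seed(2)
  ids <- matrix(sample(0:60, 8 * 20, TRUE), 8)
  toks <- structure(list(ids = ids, attention_mask = ids * 0 + 1L,
                         vocab_size = 70L), class = "token_sequences")
  m0 <- pose_transformer(toks, rep(1:2, 4),
                         model_config("tiny", n_classes = 12),
                         train_config(epochs = 0, seed = 1))
  pred <- predict(m0, toks)
  ll <- -mean(log(pred$prob[cbind(1:8, sample(1:12, 8, TRUE))]))
  expect_equal(ll, log(12), tolerance = 0.15)
  # zero epochs leaves the initialization untouched and history empty
  expect_equal(nrow(m0$history), 0)
})

test_that("the tiny preset overfits separable windows to 100% train accuracy", {
  m <- pose_transformer(local_toy$tokens, local_toy$labels,
                        model_config("tiny", n_classes = 2),
                        train_config(epochs = 20, learning_rate = 1e-3,
                                     batch_size = 16, seed = 11))
  expect_equal(max(m$history$train_acc), 1)
  expect_lt(min(m$history$train_loss), 0.1)
})

test_that("prediction is deterministic, batch-size invariant, and properly normalized", {
  m <- pose_transformer(local_toy$tokens, local_toy$labels,
                        model_config("tiny", n_classes = 2),
                        train_config(epochs = 2, learning_rate = 1e-3,
                                     seed = 3))
  p1 <- predict(m, local_toy$tokens, batch_size = 1)
  p2 <- predict(m, local_toy$tokens, batch_size = 16)
  p3 <- predict(m, local_toy$tokens, batch_size = 16)
  expect_identical(p2$prob, p3$prob)          # eval-mode determinism
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  expect_equal(rowSums(p1$prob), rep(1, nrow(p1$prob)), tolerance = 1e-6)
  expect_equal(p1$class, max.col(p1$prob, "first"))
})

test_that("the tiny preset reaches macro recall >= 0.90 on separable motion archetypes", {
  seqs <- generate_dataset(motion_config(setNames(rep(30L, 12), 1:12),
                                         seconds = 2, noise_sd = 2,
                                         jitter = FALSE, seed = 8))
  win <- build_windows_all(seqs, window_spec())
  cfg <- train_config(epochs = 16, learning_rate = 1e-3, seed = 4)
  idx <- split_dataset(win, cfg)
  sc <- fit_scaler(win[idx$train, ], vocab_numeric = 128)
  tr <- encode_windows(window_features(win[idx$train, ]), sc)
  va <- encode_windows(window_features(win[idx$val, ]), sc)
  te <- encode_windows(window_features(win[idx$test, ]), sc)
  m <- pose_transformer(tr, win$label[idx$train], model_config("tiny"), cfg,
                        val_tokens = va, val_labels = win$label[idx$val])
  pr <- predict(m, te)
  rep <- per_class_metrics(confusion(win$label[idx$test], pr$class, 12))
  expect_gte(rep$macro[["recall"]], 90)
})

test_that("training twice with one seed reproduces the model exactly", {
  cfg <- train_config(epochs = 2, learning_rate = 1e-3, seed = 13)
  m1 <- pose_transformer(local_toy$tokens, local_toy$labels,
                         model_config("tiny", n_classes = 2), cfg)
  m2 <- pose_transformer(local_toy$tokens, local_toy$labels,
                         model_config("tiny", n_classes = 2), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})
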