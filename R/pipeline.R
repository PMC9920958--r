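# End-to-end experiment orchestration: synth -> window -> split -> scale ->
# tokenize -> (augment) -> train -> evaluate, with a manifest that records
# every derived seed, row count and the test-split hash so that two arms
# (plain vs augmented) are only ever compared on an identical test set.

fnv1a <- function(s) {
  # polynomial rolling hash over a string (double arithmetic stays exact:
  # intermediate values < 2^53)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

split_hash <- function(windows, idx) {
  key <- paste(windows$source[idx], windows$window_start[idx],
               windows$label[idx], sep = "|", collapse = ";")
  fnv1a(key)
}

#' Experiment configuration
#'
#' Bundles every stage's settings for [run_experiment()]. All randomness
#' fans out from the single `seed` through [derive_seed()].
#'
#' @param workdir directory for run artifacts (created; one subdirectory
#'   per run).
#' @param synth_style,synth_budget imbalance profile and total window
#'   budget for the synthetic dataset (see [imbalance_profile()]).
#' @param noise_sd,seconds synthetic motion parameters
#'   (see [motion_config()]).
#' @param window window specification ([window_spec()]).
#' @param vocab_numeric,fit_scope tokenizer settings ([fit_scaler()]).
#' @param model classifier architecture ([model_config()]).
#' @param train training settings ([train_config()]); its `seed` and
#'   `split_mode` are honoured.
#' @param gan GAN settings ([gan_config()]).
#' @param plan_strategy,plan_target augmentation plan
#'   (see [build_plan()]).
#' @param seed global experiment seed.
#' @return A `run_config` list.
#' @export
run_config <- function(workdir = tempfile("skelseq-run-"),
                       synth_style = "upfall_like", synth_budget = 1600L,
                       noise_sd = 4, seconds = 2,
                       window = window_spec(),
                       vocab_numeric = 30000L, fit_scope = "train",
                       model = model_config("tiny"),
                       train = train_config(),
                       gan = gan_config(),
                       plan_strategy = "target_share", plan_target = 0.05,
                       seed = 1L) {
  structure(list(workdir = workdir, synth_style = synth_style,
                 synth_budget = as.integer(synth_budget),
                 noise_sd = noise_sd, seconds = seconds, window = window,
                 vocab_numeric = as.integer(vocab_numeric),
                 fit_scope = fit_scope, model = model, train = train,
                 gan = gan, plan_strategy = plan_strategy,
                 plan_target = plan_target, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config, augment) {
  drop <- setdiff(names(config), "workdir")
  fnv1a(paste(augment,
              paste(deparse(config[drop], control = "all"), collapse = ""),
              sep = "#"))
}

#' Run one experiment arm
#'
#' Executes the full protocol on synthetic motion data (or supplied
#' sequences): generate sequences, cut windows, split 70/15/15, fit the
#' tokenizer scaler on the training split, optionally train the
#' conditional GAN on the training rows and append its synthetic
#' minority-class rows to the training partition only, train the
#' classifier, and evaluate on the untouched real test windows. Every
#' artifact (window table, scaler JSON, synthetic rows, diagnostics,
#' metrics, confusion matrix, history, manifest) is written to the run
#' directory.
#'
#' @param config a [run_config()].
#' @param augment add GAN-synthesised minority rows to the training set.
#' @param sequences optional list of [pose_sequence()] objects; when NULL,
#'   synthetic data is generated per the config.
#' @param test_sequences optional external evaluation sequences. When
#'   supplied, the model is evaluated on windows cut from them instead of
#'   the internal test partition (set the config's test fraction to 0 so
#'   no training data is wasted). Useful at desk scale, where a 15% split
#'   of sub-1% classes leaves only one or two test windows per class.
#' @param run_name subdirectory name (default derived from `augment`).
#' @param verbose print stage progress.
#' @return The run directory path (invisibly, with the full result list as
#'   attribute `"result"`).
#' @export
run_experiment <- function(config, augment = FALSE, sequences = NULL,
                           test_sequences = NULL, run_name = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  run_name <- run_name %||% if (augment) "augmented" else "plain"
  run_dir <- file.path(config$workdir, run_name)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(run_name = run_name, augment = augment,
                   seed = config$seed,
                   config_hash = config_hash(config, augment))
  stage <- "synth"
  tryCatch({
    # ---- data
    if (is.null(sequences)) {
      wc <- imbalance_profile(config$synth_style, config$synth_budget)
      sc <- sequences_for_windows(wc, config$seconds, 18, config$window)
      mc <- motion_config(sc, fps = 18, seconds = config$seconds,
                          noise_sd = config$noise_sd,
                          seed = derive_seed(config$seed, "synth"))
      sequences <- generate_dataset(mc)
      manifest$n_sequences <- length(sequences)
      say("synth: %d sequences", length(sequences))
    }
    # ---- windows
    stage <- "window"
    windows <- build_windows_all(sequences, config$window)
    if (nrow(windows) == 0L) stop("no usable windows")
    manifest$n_windows <- nrow(windows)
    manifest$n_dropped <- attr(windows, "n_dropped")
    utils::write.csv(windows, file.path(run_dir, "windows.csv"),
                     row.names = FALSE)
    say("window: %d windows", nrow(windows))
    # ---- split
    stage <- "split"
    tcfg <- config$train
    tcfg$seed <- derive_seed(config$seed, "split")
    idx <- split_dataset(windows, tcfg)
    if (is.null(test_sequences)) {
      test_windows <- windows[idx$test, ]
      manifest$external_test <- FALSE
    } else {
      test_windows <- build_windows_all(test_sequences, config$window)
      manifest$external_test <- TRUE
    }
    manifest$n_train <- length(idx$train)
    manifest$n_val <- length(idx$val)
    manifest$n_test <- nrow(test_windows)
    manifest$test_split_hash <- split_hash(test_windows,
                                           seq_len(nrow(test_windows)))
    # ---- scaler
    stage <- "scaler"
    fit_rows <- if (config$fit_scope == "all") seq_len(nrow(windows)) else idx$train
    scaler <- fit_scaler(windows[fit_rows, ], config$vocab_numeric,
                         config$fit_scope)
    write_scaler(scaler, file.path(run_dir, "scaler.json"))
    # ---- augmentation
    stage <- "augment"
    train_feat <- window_features(windows[idx$train, ])
    train_lab <- windows$label[idx$train]
    fake <- NULL
    if (augment) {
      gcfg <- config$gan
      gcfg$seed <- derive_seed(config$seed, "gan")
      gan <- tabular_gan(train_feat, train_lab, gcfg, n_classes = 12L)
      counts <- tabulate(train_lab, 12L)
      plan <- build_plan(counts, config$plan_strategy,
                         target = config$plan_target)
      fake_parts <- lapply(which(plan > 0), function(cl) {
        generate(gan, cl, plan[cl],
                 seed = derive_seed(config$seed, paste0("gen", cl)))
      })
      fake <- do.call(rbind, fake_parts)
      manifest$n_fake <- if (is.null(fake)) 0L else nrow(fake)
      if (!is.null(fake) && nrow(fake)) {
        utils::write.csv(fake, file.path(run_dir, "synthetic-rows.csv"),
                         row.names = FALSE)
        diag <- gan_diagnostics(train_feat, fake[, -1, drop = FALSE])
        utils::write.csv(diag, file.path(run_dir, "gan-diagnostics.csv"),
                         row.names = FALSE)
      }
      say("augment: %d synthetic rows", manifest$n_fake)
    }
    # ---- tokenize
    stage <- "tokenize"
    feat_all <- rbind(train_feat,
                      if (!is.null(fake)) as.matrix(fake[, -1, drop = FALSE]))
    lab_all <- c(train_lab, if (!is.null(fake)) fake$label)
    tr_tok <- encode_windows(feat_all, scaler)
    va_tok <- encode_windows(window_features(windows[idx$val, ]), scaler)
    te_tok <- encode_windows(window_features(test_windows), scaler)
    manifest$n_train_total <- nrow(tr_tok$ids)
    # ---- train
    stage <- "train"
    tcfg$seed <- derive_seed(config$seed, "train")
    model <- pose_transformer(tr_tok, lab_all, config$model, tcfg,
                              val_tokens = va_tok,
                              val_labels = windows$label[idx$val],
                              verbose = verbose)
    utils::write.csv(model$history, file.path(run_dir, "history.csv"),
                     row.names = FALSE)
    # ---- evaluate
    stage <- "evaluate"
    pred <- predict(model, te_tok)
    y_true <- test_windows$label
    cm <- confusion(y_true, pred$class, config$model$n_classes)
    report <- per_class_metrics(cm)
    write_metrics_csv(report, file.path(run_dir, "metrics.csv"))
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(run_dir, "confusion.csv"))
    jsonlite::write_json(
      list(per_class = report$per_class, macro = as.list(report$macro),
           n = report$n),
      file.path(run_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    manifest$macro_f1 <- unname(report$macro["f1"])
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("evaluate: macro F1 %.2f", manifest$macro_f1)
    result <- list(run_dir = run_dir, manifest = manifest, model = model,
                   report = report, cm = cm, windows = windows, idx = idx,
                   scaler = scaler)
    out <- run_dir
    attr(out, "result") <- result
    invisible(out)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

read_metrics_report <- function(run_dir) {
  obj <- jsonlite::fromJSON(file.path(run_dir, "metrics.json"))
  structure(list(per_class = as.data.frame(obj$per_class),
                 macro = unlist(obj$macro), n = obj$n),
            class = "metrics_report")
}

#' Compare two completed experiment arms
#'
#' Loads both run directories' metrics and manifests, verifies that the
#' arms were evaluated on the bit-identical test split (hash check; the
#' comparison is meaningless otherwise) and returns the macro-metric and
#' per-class recall deltas together with the configuration difference.
#'
#' @param run_a,run_b run directories from [run_experiment()] (run `a` is
#'   the baseline).
#' @return An `arm_comparison`: the [compare_runs()] result plus manifest
#'   info.
#' @export
compare_arms <- function(run_a, run_b) {
  man_a <- jsonlite::fromJSON(file.path(run_a, "manifest.json"))
  man_b <- jsonlite::fromJSON(file.path(run_b, "manifest.json"))
  if (!identical(man_a$test_split_hash, man_b$test_split_hash)) {
    stop("test split hashes differ (", man_a$test_split_hash, " vs ",
         man_b$test_split_hash, "); arms are not comparable")
  }
  rep_a <- read_metrics_report(run_a)
  rep_b <- read_metrics_report(run_b)
  cmp <- compare_runs(rep_a, rep_b)
  config_delta <- if (identical(man_a$config_hash, man_b$config_hash)) {
    "none"
  } else if (man_a$augment != man_b$augment) {
    "augmentation"
  } else {
    "other"
  }
  structure(list(comparison = cmp, config_delta = config_delta,
                 manifest_a = man_a, manifest_b = man_b),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("arm comparison (%s vs %s); config delta: %s\n",
              x$manifest_a$run_name, x$manifest_b$run_name,
              x$config_delta))
  print(x$comparison)
  invisible(x)
}
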