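test_that("training-by-sampling draws conditions proportional to frequency", {
  expect_equal(unique(sample_condition(c(1, 0, 0), 200)), 1L)
  set.seed(12)
  draws <- sample_condition(c(1, 1), 10000)
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.02)
  draws2 <- sample_condition(c(3, 1), 10000)
  expect_equal(mean(draws2 == 1), 0.75, tolerance = 0.02)
  expect_error(sample_condition(c(0, 0), 1), "zero")
  # log-frequency flattens towards rare classes
  set.seed(13)
  raw <- mean(sample_condition(c(99, 1), 10000) == 2)
  lg <- mean(sample_condition(c(99, 1), 10000, log_frequency = TRUE) == 2)
  expect_gt(lg, raw)
})

test_that("augmentation plans reproduce the published counts and target shares", {
  tab <- upfall_tables()$windows
  plan <- build_plan(tab$n_true, strategy = "published")
  expect_equal(sum(plan), 84065L)
  expect_equal(unname(plan[1]), 17267L)
  expect_equal(unname(plan[7:9]), c(0L, 0L, 0L))
  # dataset growth of about 40%
  expect_gt(sum(plan) / sum(tab$n_true), 0.40)

  # 2-class 90/10 fixture raised to a 50% share needs 80 synthetic rows
  p2 <- build_plan(c(90, 10), strategy = "target_share", target = 0.5)
  expect_equal(unname(p2), c(0L, 80L))

  # already balanced -> all-zero plan
  p3 <- build_plan(c(50, 50), strategy = "target_share", target = 0.3)
  expect_true(all(p3 == 0))
  expect_error(build_plan(c(-1, 5), "target_share", target = 0.2), "negative")
})

test_that("diagnostics quantify real/synthetic agreement per feature", {
  set.seed(14)
  real <- matrix(rnorm(600), 100, 6,
                 dimnames = list(NULL, paste0("f00", 1:6)))
  self_diag <- gan_diagnostics(real, real)
  expect_equal(self_diag$mean_real, self_diag$mean_fake)
  expect_equal(self_diag$cdf_gap, rep(0, 6))

  shifted <- real + 2
  d2 <- gan_diagnostics(real, shifted)
  expect_equal(d2$mean_fake - d2$mean_real, rep(2, 6))
  expect_equal(d2$sd_fake, d2$sd_real)

  expect_error(gan_diagnostics(real, real[, 1:3]), "columns")
})

test_that("the conditional GAN trains, conditions exactly, and is seed-deterministic", {
  # 2 classes x 2 features with class-dependent means; a short run checks
  # the mechanics (full distribution-recovery runs live in the acceptance
  # suite)
  set.seed(11)
  n <- 200
  feats <- rbind(cbind(rnorm(n, 2, 1), rnorm(n, -1, 0.5)),
                 cbind(rnorm(n, -2, 1), rnorm(n, 3, 0.5)))
  colnames(feats) <- c("f001", "f002")
  labs <- rep(1:2, each = n)
  gan <- tabular_gan(feats, labs,
                     gan_config(generator_dims = c(32, 32),
                                discriminator_dims = c(32, 32),
                                noise_dim = 16, epochs = 60,
                                batch_size = 40, pac = 4, seed = 5),
                     n_classes = 2)
  expect_true(all(is.finite(gan$history$d_loss)))
  for (cl in 1:2) {
    fake <- generate(gan, cl, 50, seed = 100 + cl)
    expect_equal(nrow(fake), 50)
    expect_true(all(fake$label == cl))   # conditional integrity
    expect_equal(names(fake), c("label", "f001", "f002"))
    expect_true(all(is.finite(as.matrix(fake[, -1]))))
  }
  # empty request; unknown class
  expect_equal(nrow(generate(gan, 1, 0)), 0)
  expect_error(generate(gan, 3, 5), "unknown class")
  # determinism of training under a fixed seed
  gan2 <- tabular_gan(feats[c(1:50, 201:250), ], labs[c(1:50, 201:250)],
                      gan_config(generator_dims = c(16, 16),
                                 discriminator_dims = c(16, 16),
                                 noise_dim = 8, epochs = 3,
                                 batch_size = 20, pac = 4, seed = 7),
                      n_classes = 2)
  gan3 <- tabular_gan(feats[c(1:50, 201:250), ], labs[c(1:50, 201:250)],
                      gan_config(generator_dims = c(16, 16),
                                 discriminator_dims = c(16, 16),
                                 noise_dim = 8, epochs = 3,
                                 batch_size = 20, pac = 4, seed = 7),
                      n_classes = 2)
  expect_identical(gan2$g_params, gan3$g_params)
  # generation is seeded and labeled with the requested class
  f1 <- generate(gan2, 2, 10, seed = 3)
  f2 <- generate(gan2, 2, 10, seed = 3)
  expect_identical(f1, f2)
})
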