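test_that("configs are validated before any training happens", {
  expect_error(tiny_experiment(mode = "coteaching_conventional"),
               "tau")
  train <- make_ring_task(ring_task_spec(6, 10, seed = 1))
  expect_error(experiment_config(
    train = list(features = train$features, labels = train$labels[-1]),
    test = list(features = train$features, labels = train$labels),
    mode = "standard"), "matching")
  expect_error(tiny_experiment(epochs = 0), "positive")
})

test_that("standard training masters the noise-free task quickly", {
  cfg <- tiny_experiment(mode = "standard", epochs = 50, sigma = 0.05)
  run <- run_experiment(cfg)
  expect_gt(run$summary$accuracy_mean, 0.98)
  expect_equal(run$summary$rejection_mean, 0)
})

test_that("runs are reproducible and summaries recompute from the log", {
  cfg <- tiny_experiment(epochs = 6, noise = noise_spec("uniform", 0.2, 6))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$log, r2$log)
  expect_equal(r1$summary$rejection_mean,
               mean(tail(r1$log$rejection_rate, 6)))
  expect_equal(r1$summary$accuracy_mean,
               mean(c(tail(r1$log$accuracy_model1, 6),
                      tail(r1$log$accuracy_model2, 6))))
  # epoch CSVs land in out_dir and reproduce the in-memory log
  od <- tempfile()
  cfg$out_dir <- od
  run_experiment(cfg)
  got <- read.csv(file.path(od, "epochs.csv"))
  expect_equal(got$rejection_rate, r1$log$rejection_rate)
  unlink(od, recursive = TRUE)
})

test_that("a never-activating schedule reproduces standard training exactly", {
  noise <- noise_spec("uniform", 0.2, 6)
  delayed <- tiny_experiment(epochs = 8, noise = noise, n0 = 1000)
  standard <- tiny_experiment(mode = "standard", epochs = 8, noise = noise)
  r_delayed <- run_experiment(delayed)
  r_standard <- run_experiment(standard)
  expect_equal(r_delayed$log$accuracy_model1, r_standard$log$accuracy_model1)
  expect_equal(r_delayed$log$accuracy_model2, r_standard$log$accuracy_model2)
  expect_equal(r_delayed$log$rejection_rate, rep(0, 8))
  expect_equal(r_delayed$log$mean_threshold, rep(0, 8))
})

test_that("warm-up epochs log a rejection rate of exactly zero", {
  cfg <- tiny_experiment(epochs = 4, noise = noise_spec("bias", 0.45, 6),
                         n0 = 10, delta = 10)
  run <- run_experiment(cfg)
  expect_identical(run$log$rejection_rate, rep(0, 4))
  expect_identical(run$log$resamples, rep(0L, 4))
})

test_that("beta-grid sweeps reduce to single runs and are deterministic", {
  cfg <- tiny_experiment(epochs = 4, noise = noise_spec("uniform", 0.2, 6))
  single <- run_experiment(cfg)
  grid <- sweep_alpha_beta(cfg, 32, 2)
  expect_equal(nrow(grid), 1L)
  expect_equal(grid$accuracy_mean, single$summary$accuracy_mean)
  # duplicated settings give identical cells
  dup <- sweep_alpha_beta(cfg, c(8, 8), 2)
  expect_equal(dup[1, -(1:2)], dup[2, -(1:2)], ignore_attr = TRUE)
})

test_that("forget-rate sweeps aggregate repeats and punish overestimation", {
  cfg <- tiny_experiment(mode = "coteaching_conventional", epochs = 12,
                         noise = noise_spec("uniform", 0.2, 6),
                         tau = 0.2, T_k = 5)
  one <- sweep_forget_rate(cfg, rates = 0.2, repeats = 1)
  expect_equal(one$accuracy_min, one$accuracy_mean)
  expect_equal(one$accuracy_max, one$accuracy_mean)
  # rate 0 keeps everything
  zero <- run_experiment(local({c2 <- cfg
    c2$conv_cfg <- conventional_coteach_config(0, 5); c2}))
  expect_equal(zero$summary$rejection_mean, 0)
  # an extreme forget rate on mild noise is worse than a matched one
  swept <- sweep_forget_rate(cfg, rates = c(0.2, 0.95), repeats = 2)
  expect_lt(swept$accuracy_mean[swept$rate == 0.95],
            swept$accuracy_mean[swept$rate == 0.2])
})

test_that("overlap and surface metrics match their definitions", {
  a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(mean_surface_distance(a, a), 0)

  b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
  expect_equal(dice(a, b), 0)

  # two single-pixel "unit squares" offset by 3 pixels
  p1 <- matrix(FALSE, 8, 8); p1[2, 2] <- TRUE
  p2 <- matrix(FALSE, 8, 8); p2[2, 5] <- TRUE
  expect_equal(hausdorff(p1, p2), 3)
  expect_equal(mean_surface_distance(p1, p2), 3)
  # physical spacing scales distances
  expect_equal(hausdorff(p1, p2, spacing = c(1, 1.25)), 3.75)

  expect_error(hausdorff(a, matrix(FALSE, 10, 10)), "foreground")
  expect_error(dice(a, matrix(FALSE, 3, 3)), "same shape")
})

test_that("surface metrics agree with the brute-force oracle", {
  set.seed(91)
  for (i in 1:25) {
    ma <- random_blob_mask(16L)
    mb <- random_blob_mask(16L)
    oracle <- oracle_surface_dists(ma, mb)
    expect_equal(hausdorff(ma, mb), oracle$hd)
    expect_equal(mean_surface_distance(ma, mb), oracle$msd)
  }
})
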