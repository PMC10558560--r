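test_that("threshold selection keeps units at or above the threshold", {
  expect_equal(select_units(c(0.9, 0.2, 0.5), 0.5), c(TRUE, FALSE, TRUE))
  expect_true(all(select_units(runif(20), 0)))
  expect_equal(select_units(c(0.5, 0.5), 0.5), c(TRUE, TRUE))  # >= at ties
  expect_error(select_units(c(0.5), 1.5), "0, 1")
})

test_that("raising the threshold never grows the keep-mask", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(5:60, 1))
    thresholds <- sort(runif(5))
    masks <- lapply(thresholds, function(t) select_units(p, t))
    for (j in seq_len(length(masks) - 1L)) {
      expect_true(all(masks[[j]] | !masks[[j + 1L]]))  # mask j+1 subset of j
    }
  }
})

test_that("a quantile threshold reproduces keep-lowest-loss selection", {
  # cross-entropy is monotone decreasing in the posterior, so keeping the
  # k largest posteriors equals keeping the k smallest losses
  set.seed(32)
  for (i in 1:20) {
    p <- runif(40)
    batch <- unit_batch(p)  # losses default to -log(p), no ties a.s.
    f <- runif(1, 0.1, 0.9)
    k <- ceiling((1 - f) * 40)
    thr <- sort(p, decreasing = TRUE)[k]
    expect_equal(select_units(batch, thr), conventional_select(batch, f))
  }
})

test_that("stochastic selection redraws then requests a resample", {
  cfg <- default_cfg()
  # every admissible clamped threshold (>= 0.01) rejects posteriors 0.005
  hopeless <- unit_batch(rep(0.005, 64))
  set.seed(41)
  out <- stochastic_select(hopeless, cfg, no_ramp(), n = 1)
  expect_equal(out$attempts, 5L)
  expect_true(out$resample_requested)
  expect_false(any(out$keep_mask))

  confident <- unit_batch(rep(0.999, 64))
  set.seed(42)
  out2 <- stochastic_select(confident, cfg, no_ramp(), n = 1)
  expect_equal(out2$attempts, 1L)
  expect_false(out2$resample_requested)
  expect_true(all(out2$keep_mask))

  # half the batch above any admissible threshold: first draw suffices
  mixed <- unit_batch(rep(c(0.999, 0.001), each = 32))
  for (s in 1:10) {
    set.seed(400 + s)
    out3 <- stochastic_select(mixed, cfg, no_ramp(), n = 1)
    expect_equal(out3$attempts, 1L)
    expect_gte(mean(out3$keep_mask), 0.5)
  }

  # warm-up threshold is 0: everything kept regardless of posteriors
  set.seed(43)
  out4 <- stochastic_select(hopeless, cfg, ramp10(), n = 5)
  expect_true(all(out4$keep_mask))
})

test_that("conventional selection matches the sort oracle", {
  expect_equal(conventional_select(c(3, 1, 2), 1 / 3),
               c(FALSE, TRUE, TRUE))
  expect_true(all(conventional_select(runif(10), 0)))
  # stable tie-break: equal losses keep the earliest indices
  expect_equal(conventional_select(rep(1, 5), 0.5),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    losses <- sample(round(runif(n, 0, 5), 1))  # ties likely
    f <- runif(1)
    expect_identical(conventional_select(losses, f),
                     oracle_conventional_select(losses, f))
  }
})

test_that("forget rate ramps linearly to tau", {
  cfg <- conventional_coteach_config(0.5, 10)
  expect_equal(forget_rate_at(0, cfg), 0)
  expect_equal(forget_rate_at(5, cfg), 0.25)
  expect_equal(forget_rate_at(10, cfg), 0.5)
  expect_equal(forget_rate_at(200, cfg), 0.5)
  expect_error(conventional_coteach_config(1.5, 10))
})

test_that("cross-update trains each learner on the other's selection", {
  set.seed(61)
  x <- matrix(rnorm(40), 20, 2)
  y <- sample.int(3, 20, replace = TRUE)
  a0 <- make_learner("mlp_classifier", 1, d_in = 2, n_classes = 3)
  b0 <- make_learner("mlp_classifier", 2, d_in = 2, n_classes = 3)

  # selector returning a different fixed mask per call: first call sees
  # learner A's units, second call learner B's
  masks <- list(c(rep(TRUE, 5), rep(FALSE, 15)),
                c(rep(FALSE, 15), rep(TRUE, 5)))
  call_i <- 0
  fixed_selector <- function(batch, n) {
    call_i <<- call_i + 1
    structure(list(keep_mask = masks[[call_i]], threshold_used = 0,
                   attempts = 1L, resample_requested = FALSE),
              class = "selection_outcome")
  }
  step <- coteach_step(a0, b0, x, y, fixed_selector, n = 1, lr = 1e-2)
  # A must have trained on B's mask (masks[[2]]), B on A's (masks[[1]])
  a_manual <- learner_update(a0, x[masks[[2]], ], y[masks[[2]]], lr = 1e-2)
  b_manual <- learner_update(b0, x[masks[[1]], ], y[masks[[1]]], lr = 1e-2)
  expect_equal(step$learner_a$net$W, a_manual$net$W)
  expect_equal(step$learner_b$net$W, b_manual$net$W)
  # asymmetry: A trained on its own mask would differ
  a_wrong <- learner_update(a0, x[masks[[1]], ], y[masks[[1]]], lr = 1e-2)
  expect_false(isTRUE(all.equal(step$learner_a$net$W, a_wrong$net$W)))
})

test_that("keep-all co-teaching equals a standard step on the full batch", {
  set.seed(62)
  x <- matrix(rnorm(60), 30, 2)
  y <- sample.int(3, 30, replace = TRUE)
  a0 <- make_learner("mlp_classifier", 3, d_in = 2, n_classes = 3)
  b0 <- make_learner("mlp_classifier", 4, d_in = 2, n_classes = 3)
  step <- coteach_step(a0, b0, x, y, keep_all_selector(), n = 1, lr = 1e-3)
  expect_equal(step$learner_a$net, learner_update(a0, x, y, lr = 1e-3)$net)
  expect_equal(step$learner_b$net, learner_update(b0, x, y, lr = 1e-3)$net)
  expect_equal(epoch_rejection_rate(list(step$outcome_a, step$outcome_b)), 0)
})

test_that("coteach_step with the conventional selector reproduces the sorted update set", {
  set.seed(63)
  x <- matrix(rnorm(64), 32, 2)
  y <- sample.int(4, 32, replace = TRUE)
  a0 <- make_learner("mlp_classifier", 5, d_in = 2, n_classes = 4)
  b0 <- make_learner("mlp_classifier", 6, d_in = 2, n_classes = 4)
  ccfg <- conventional_coteach_config(0.25, 1)
  step <- coteach_step(a0, b0, x, y, conventional_selector(ccfg), n = 1)
  losses_a <- instance_units(predict_posteriors(a0, x), y)$losses
  expect_identical(step$outcome_a$keep_mask,
                   oracle_conventional_select(losses_a, 0.25))
  expect_error(coteach_step(a0, b0, x[0, , drop = FALSE], integer(0),
                            keep_all_selector(), 1), "empty")
})

test_that("a resample request aborts the update and counts all units rejected", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(1:2, 5)
  a0 <- make_learner("mlp_classifier", 7, d_in = 2, n_classes = 2)
  b0 <- make_learner("mlp_classifier", 8, d_in = 2, n_classes = 2)
  resampler <- function(batch, n) {
    structure(list(keep_mask = rep(FALSE, length(batch$posteriors_true)),
                   threshold_used = 0.9, attempts = 5L,
                   resample_requested = TRUE),
              class = "selection_outcome")
  }
  step <- coteach_step(a0, b0, x, y, resampler, n = 1)
  expect_true(step$resampled)
  expect_equal(step$learner_a$net, a0$net)
  expect_true(is.na(step$loss_a))
  expect_equal(epoch_rejection_rate(list(step$outcome_a, step$outcome_b)), 1)
})

test_that("rejection accounting and the last-k noise estimate", {
  keep <- function(k, n) {
    structure(list(keep_mask = c(rep(TRUE, k), rep(FALSE, n - k)),
                   threshold_used = 0.5, attempts = 1L,
                   resample_requested = FALSE),
              class = "selection_outcome")
  }
  expect_equal(epoch_rejection_rate(list(keep(550, 1000))), 0.45)
  expect_equal(epoch_rejection_rate(list(keep(10, 10), keep(10, 10))), 0)
  expect_error(epoch_rejection_rate(list()), "no selection")

  logs <- data.frame(epoch = 1:12, rejection_rate = rep(0.45, 12))
  est <- estimate_noise_rate(logs)
  expect_equal(est$mean, 0.45)
  expect_equal(est$sd, 0)
  alt <- data.frame(rejection_rate = c(0.3, rep(c(0.19, 0.21), 5)))
  expect_equal(estimate_noise_rate(alt)$mean, 0.20)
  expect_error(estimate_noise_rate(data.frame(rejection_rate = 0.5)),
               "at least")
})
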