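# Shared fixture builders; everything is generated in code at test time.

default_cfg <- function(...) beta_threshold_config(32, 2, ...)
ramp10 <- function() threshold_schedule(10, 10)
no_ramp <- function() threshold_schedule(0, 1)  # full strength from n = 1

# small noisy ring-task experiment config for fast loop tests
tiny_experiment <- function(mode = "coteaching_stochastic", epochs = 5L,
                            noise = NULL, sigma = 0.15, seed = 7L, ...) {
  train <- make_ring_task(ring_task_spec(6, 120, sigma = sigma, seed = 101))
  test <- make_ring_task(ring_task_spec(6, 40, sigma = sigma, seed = 102))
  labels <- train$labels
  if (!is.null(noise)) {
    set.seed(303)
    labels <- corrupt_labels(labels, noise)$noisy
  }
  experiment_config(
    train = list(features = train$features, labels = labels),
    test = list(features = test$features, labels = test$labels),
    mode = mode, epochs = epochs, batch_size = 64L, seed = seed, ...)
}

# CDF of a Beta(a, b) draw clamped into [lo, hi]
clamped_beta_cdf <- function(t, a, b, lo = 0.01, hi = 0.99) {
  ifelse(t < lo, 0, ifelse(t < hi, pbeta(t, a, b), 1))
}

# independent brute-force keep-lowest-loss selection (sort oracle)
oracle_conventional_select <- function(losses, forget_rate) {
  n <- length(losses)
  k <- ceiling((1 - forget_rate) * n)
  keep <- logical(n)
  if (k == 0L) return(keep)
  ord <- sort.int(losses, index.return = TRUE, method = "radix")$ix
  keep[ord[seq_len(k)]] <- TRUE
  keep
}

# naive boundary extraction: explicit neighbor checks per pixel
oracle_boundary <- function(mask) {
  m <- as.matrix(mask) != 0
  pts <- NULL
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j]) next
    edge <- i == 1L || j == 1L || i == nrow(m) || j == ncol(m)
    if (edge || !m[i - 1L, j] || !m[i + 1L, j] ||
        !m[i, j - 1L] || !m[i, j + 1L]) {
      pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

# double-loop surface distances between two masks
oracle_surface_dists <- function(mask_a, mask_b, spacing = c(1, 1)) {
  pa <- oracle_boundary(mask_a)
  pb <- oracle_boundary(mask_b)
  d_ab <- numeric(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    best <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt(((pa[i, 1] - pb[j, 1]) * spacing[1])^2 +
                ((pa[i, 2] - pb[j, 2]) * spacing[2])^2)
      if (d < best) best <- d
    }
    d_ab[i] <- best
  }
  d_ba <- numeric(nrow(pb))
  for (j in seq_len(nrow(pb))) {
    best <- Inf
    for (i in seq_len(nrow(pa))) {
      d <- sqrt(((pa[i, 1] - pb[j, 1]) * spacing[1])^2 +
                ((pa[i, 2] - pb[j, 2]) * spacing[2])^2)
      if (d < best) best <- d
    }
    d_ba[j] <- best
  }
  list(hd = max(max(d_ab), max(d_ba)),
       msd = (mean(d_ab) + mean(d_ba)) / 2)
}

# random blob mask guaranteed non-empty
random_blob_mask <- function(size = 32L) {
  m <- matrix(FALSE, size, size)
  for (b in seq_len(sample(1:3, 1))) {
    cx <- runif(1, 4, size - 4); cy <- runif(1, 4, size - 4)
    r <- runif(1, 1.5, 6)
    xs <- matrix(rep(seq_len(size), times = size), size, size)
    ys <- matrix(rep(seq_len(size), each = size), size, size)
    m <- m | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  if (!any(m)) m[sample(size, 1), sample(size, 1)] <- TRUE
  m
}
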