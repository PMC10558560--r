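# Selection logic, the co-teaching cross-update step, and rejection-rate
# accounting.

#' Bundle per-unit posteriors and losses for selection
#'
#' A *unit* is whatever granularity selection operates at: a whole instance
#' (single-label classification), an (instance, label) pair (multi-label),
#' or a pixel (dense segmentation). `posteriors_true` holds the model's
#' posterior probability for each unit's *recorded* (possibly noisy) label
#' — the selection statistic.
#'
#' @param posteriors_true Numeric vector in `[0, 1]`, one entry per unit.
#' @param losses Optional non-negative per-unit losses; defaults to the
#'   cross-entropy `-log(posteriors_true)`.
#' @param granularity One of `"instance"`, `"instance_label"`, `"pixel"`.
#' @return An object of class `unit_batch`.
#' @export
unit_batch <- function(posteriors_true, losses = NULL,
                       granularity = c("instance", "instance_label", "pixel")) {
  granularity <- match.arg(granularity)
  if (length(posteriors_true) < 1L) {
    stop("a unit batch must contain at least one unit", call. = FALSE)
  }
  if (any(posteriors_true < 0 | posteriors_true > 1)) {
    stop("`posteriors_true` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(losses)) losses <- -log(posteriors_true)
  if (length(losses) != length(posteriors_true)) {
    stop("`losses` and `posteriors_true` must have equal length", call. = FALSE)
  }
  if (any(losses < 0)) stop("`losses` must be non-negative", call. = FALSE)
  structure(list(posteriors_true = as.numeric(posteriors_true),
                 losses = as.numeric(losses),
                 granularity = granularity),
            class = "unit_batch")
}

#' @export
print.unit_batch <- function(x, ...) {
  cat(sprintf("Unit batch: %d %s units, posterior range [%.3g, %.3g]\n",
              length(x$posteriors_true), x$granularity,
              min(x$posteriors_true), max(x$posteriors_true)))
  invisible(x)
}

#' Threshold selection of training units
#'
#' Keeps unit `i` iff `posteriors_true[i] >= threshold` (units exactly at
#' the threshold are kept, so a threshold of 0 keeps everything).
#'
#' @param batch A [unit_batch()] or a bare numeric vector of posteriors.
#' @param threshold A single threshold in `[0, 1]`.
#' @return Logical keep-mask, one entry per unit.
#' @export
select_units <- function(batch, threshold) {
  p <- if (inherits(batch, "unit_batch")) batch$posteriors_true else batch
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single number in [0, 1]", call. = FALSE)
  }
  p >= threshold
}

new_selection_outcome <- function(keep_mask, threshold_used, attempts,
                                  resample_requested) {
  structure(list(keep_mask = keep_mask, threshold_used = threshold_used,
                 attempts = as.integer(attempts),
                 resample_requested = isTRUE(resample_requested)),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf(
    "Selection: kept %d/%d units (attempts %d%s), mean threshold %.3g\n",
    sum(x$keep_mask), length(x$keep_mask), x$attempts,
    if (x$resample_requested) ", resample requested" else "",
    mean(x$threshold_used)))
  invisible(x)
}

#' Stochastic selection with stability safeguards
#'
#' Draws a beta threshold via [sample_threshold()] and applies
#' [select_units()]. If fewer than `min_frac` of the units are kept, a new
#' threshold is drawn, up to `max_attempts` times. If every attempt fails
#' the mini-batch may consist almost entirely of noisy units: an empty
#' keep-mask is returned with `resample_requested = TRUE` so the caller can
#' draw a fresh mini-batch.
#'
#' @param batch A [unit_batch()].
#' @param cfg A [beta_threshold_config()].
#' @param sched A [threshold_schedule()].
#' @param n Current schedule step.
#' @param min_frac Minimum kept fraction per attempt (default 0.10).
#' @param max_attempts Threshold redraws before requesting a resample
#'   (default 5).
#' @return A `selection_outcome`: `keep_mask`, `threshold_used`, `attempts`,
#'   `resample_requested`.
#' @export
stochastic_select <- function(batch, cfg, sched, n, min_frac = 0.10,
                              max_attempts = 5L) {
  stopifnot(inherits(batch, "unit_batch"))
  thr <- NA_real_
  for (attempt in seq_len(max_attempts)) {
    thr <- sample_threshold(cfg, sched, n)
    keep <- select_units(batch, thr)
    if (mean(keep) >= min_frac) {
      return(new_selection_outcome(keep, thr, attempt, FALSE))
    }
  }
  new_selection_outcome(rep(FALSE, length(batch$posteriors_true)), thr,
                        max_attempts, TRUE)
}

#' Conventional co-teaching configuration
#'
#' Conventional co-teaching rejects a pre-specified fraction (the *forget
#' rate*) of highest-loss units per mini-batch, ramped linearly from 0 to
#' `tau` over the first `T_k` epochs: the forget rate at epoch `n` is
#' `tau * min(n / T_k, 1)`. Effective use requires `tau` to be tuned to the
#' (usually unknown) noise rate.
#'
#' @param tau Target forget rate in `[0, 1]`.
#' @param T_k Positive integer ramp length in epochs.
#' @return An object of class `conventional_coteach_config`.
#' @export
conventional_coteach_config <- function(tau, T_k) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("`tau` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(T_k) || length(T_k) != 1L || T_k <= 0 || T_k != trunc(T_k)) {
    stop("`T_k` must be a single positive integer", call. = FALSE)
  }
  structure(list(tau = tau, T_k = as.integer(T_k)),
            class = "conventional_coteach_config")
}

#' Forget rate at a given epoch
#'
#' @param n Epoch index `>= 0`.
#' @param cfg A [conventional_coteach_config()].
#' @return `tau * min(n / T_k, 1)`, vectorized over `n`.
#' @export
forget_rate_at <- function(n, cfg) {
  stopifnot(inherits(cfg, "conventional_coteach_config"))
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  cfg$tau * pmin(n / cfg$T_k, 1)
}

#' Keep the lowest-loss units (conventional co-teaching selection)
#'
#' Keeps the `ceiling((1 - forget_rate) * n)` units with the smallest
#' losses; ties are broken by original position (stable), so equal-loss
#' units earlier in the batch are kept first.
#'
#' @param losses Numeric vector of per-unit losses, or a [unit_batch()].
#' @param forget_rate Fraction of highest-loss units to reject, in `[0, 1]`.
#' @return Logical keep-mask.
#' @export
conventional_select <- function(losses, forget_rate) {
  if (inherits(losses, "unit_batch")) losses <- losses$losses
  if (!is.numeric(forget_rate) || length(forget_rate) != 1L ||
      forget_rate < 0 || forget_rate > 1) {
    stop("`forget_rate` must be a single number in [0, 1]", call. = FALSE)
  }
  n <- length(losses)
  k <- ceiling((1 - forget_rate) * n)
  keep <- logical(n)
  if (k > 0L) keep[order(losses)[seq_len(k)]] <- TRUE  # order() is stable
  keep
}

#' Selector factories
#'
#' A *selector* is a function `f(batch, n)` mapping a [unit_batch()] and the
#' current epoch to a `selection_outcome`; [coteach_step()] and
#' [run_experiment()] are parameterized over it.
#' `stochastic_selector()` wraps [stochastic_select()];
#' `conventional_selector()` wraps [conventional_select()] with the ramped
#' forget rate of [forget_rate_at()]; `keep_all_selector()` keeps every unit
#' (standard training).
#'
#' @param cfg A [beta_threshold_config()] (stochastic) or
#'   [conventional_coteach_config()] (conventional).
#' @param sched A [threshold_schedule()].
#' @param min_frac,max_attempts Stability safeguards, see
#'   [stochastic_select()].
#' @return A selector function.
#' @name selectors
NULL

#' @rdname selectors
#' @export
stochastic_selector <- function(cfg, sched, min_frac = 0.10, max_attempts = 5L) {
  stopifnot(inherits(cfg, "beta_threshold_config"),
            inherits(sched, "threshold_schedule"))
  function(batch, n) stochastic_select(batch, cfg, sched, n,
                                       min_frac = min_frac,
                                       max_attempts = max_attempts)
}

#' @rdname selectors
#' @export
conventional_selector <- function(cfg) {
  stopifnot(inherits(cfg, "conventional_coteach_config"))
  function(batch, n) {
    f <- forget_rate_at(n, cfg)
    new_selection_outcome(conventional_select(batch$losses, f), f, 1L, FALSE)
  }
}

#' @rdname selectors
#' @export
keep_all_selector <- function() {
  function(batch, n) {
    new_selection_outcome(rep(TRUE, length(batch$posteriors_true)), 0, 1L, FALSE)
  }
}

#' One co-teaching mini-batch step (cross-update)
#'
#' Each learner predicts posteriors for the mini-batch; the selector is
#' applied to each learner's own posteriors; then each learner is updated on
#' the units *the other* learner selected. The asymmetry is the point: a
#' learner never filters its own training signal, so the two decision
#' boundaries stay decoupled. Losses are averaged over kept units only, so
#' the gradient scale does not depend on the keep-count.
#'
#' If either selection requests a resample, no update is performed and
#' `resampled = TRUE` is returned so the caller can draw a fresh mini-batch.
#'
#' @param learner_a,learner_b Learners from [make_learner()].
#' @param x Mini-batch features (rows = instances).
#' @param y Integer labels in `1..C` for the mini-batch.
#' @param selector A selector function, see [selectors].
#' @param n Current epoch (passed to the selector and schedule).
#' @param lr Learning rate for the update.
#' @return A list: updated `learner_a`, `learner_b`, mean kept-unit losses
#'   `loss_a`, `loss_b` (`NA` on resample), the two `selection_outcome`s
#'   (`outcome_a`, `outcome_b`), and `resampled`.
#' @export
coteach_step <- function(learner_a, learner_b, x, y, selector, n, lr = 1e-3) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty mini-batch", call. = FALSE)
  units_a <- instance_units(predict_posteriors(learner_a, x), y)
  units_b <- instance_units(predict_posteriors(learner_b, x), y)
  out_a <- selector(units_a, n)
  out_b <- selector(units_b, n)
  if (out_a$resample_requested || out_b$resample_requested) {
    return(list(learner_a = learner_a, learner_b = learner_b,
                loss_a = NA_real_, loss_b = NA_real_,
                outcome_a = out_a, outcome_b = out_b, resampled = TRUE))
  }
  # cross-update: A trains on B's selection and vice versa
  if (any(out_b$keep_mask)) {
    learner_a <- learner_update(learner_a, x[out_b$keep_mask, , drop = FALSE],
                                y[out_b$keep_mask], lr = lr)
  }
  if (any(out_a$keep_mask)) {
    learner_b <- learner_update(learner_b, x[out_a$keep_mask, , drop = FALSE],
                                y[out_a$keep_mask], lr = lr)
  }
  list(learner_a = learner_a, learner_b = learner_b,
       loss_a = mean(units_a$losses[out_a$keep_mask]),
       loss_b = mean(units_b$losses[out_b$keep_mask]),
       outcome_a = out_a, outcome_b = out_b, resampled = FALSE)
}

#' Epoch-level rejection rate
#'
#' Total rejected units over total presented units across the epoch's
#' selection outcomes. Resampled mini-batches contribute all their units as
#' rejected — skipping them silently would bias the noise estimate downward.
#'
#' @param outcomes A list of `selection_outcome` objects (typically both
#'   learners' outcomes from every step of an epoch).
#' @return Rejection rate in `[0, 1]`.
#' @export
epoch_rejection_rate <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no selection outcomes logged", call. = FALSE)
  presented <- sum(vapply(outcomes, function(o) length(o$keep_mask), numeric(1)))
  kept <- sum(vapply(outcomes, function(o) sum(o$keep_mask), numeric(1)))
  (presented - kept) / presented
}

#' Estimate the label-noise rate from the rejection-rate trace
#'
#' Once training has converged, almost all rejected units are the
#' incorrectly labeled ones, so the converged rejection rate estimates the
#' label-noise rate. The estimate is the mean (with standard deviation) of
#' the per-epoch rejection rate over the final `k` epochs.
#'
#' @param epoch_logs A data frame with a `rejection_rate` column, one row
#'   per epoch (as produced by [run_experiment()]).
#' @param k Number of final epochs to average (default 10).
#' @return A list with `mean` and `sd`.
#' @export
estimate_noise_rate <- function(epoch_logs, k = 10L) {
  if (is.list(epoch_logs) && !is.data.frame(epoch_logs) &&
      !is.null(epoch_logs$log)) {
    epoch_logs <- epoch_logs$log
  }
  if (!is.data.frame(epoch_logs) || is.null(epoch_logs$rejection_rate)) {
    stop("`epoch_logs` must be a data frame with a `rejection_rate` column",
         call. = FALSE)
  }
  if (nrow(epoch_logs) < k) {
    stop(sprintf("need at least k = %d logged epochs, got %d",
                 k, nrow(epoch_logs)), call. = FALSE)
  }
  r <- utils::tail(epoch_logs$rejection_rate, k)
  list(mean = mean(r), sd = stats::sd(r))
}
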