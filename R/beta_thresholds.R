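# Beta-distributed selection thresholds, clamping and the ramp-in schedule.

#' Configuration for beta-distributed selection thresholds
#'
#' Selection thresholds are drawn from a \eqn{Beta(\alpha, \beta)}
#' distribution on \eqn{[0, 1]} and clamped away from 0 and 1 before being
#' scaled by the ramp-in schedule (see [threshold_schedule()]). Left-tailed
#' shapes (\eqn{\alpha > \beta}, e.g. \eqn{\alpha = 32, \beta = 2}) draw high
#' thresholds most of the time while retaining a chance of low thresholds
#' that re-admit difficult but correctly labeled units.
#'
#' @param alpha,beta Positive shape parameters. Values below 1 produce
#'   distributions with mass piling at the interval ends and trigger a
#'   warning; unimodal or uniform shapes (`alpha, beta >= 1`) are the
#'   intended operating regime.
#' @param clamp_lo,clamp_hi Clamp bounds in (0, 1), defaults 0.01 and 0.99.
#'   Clamping guarantees that units with very low recorded-label posterior
#'   are rejected and units with very high posterior are kept, and rules out
#'   the degenerate thresholds 0 (keep everything) and 1 (empty selection).
#' @return An object of class `beta_threshold_config`.
#' @seealso [sample_threshold()], [beta_pdf()]
#' @examples
#' cfg <- beta_threshold_config(32, 2)
#' set.seed(1)
#' sample_threshold(cfg, threshold_schedule(0, 1), n = 5)
#' @export
beta_threshold_config <- function(alpha, beta, clamp_lo = 0.01, clamp_hi = 0.99) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 ||
      !is.numeric(beta)  || length(beta)  != 1L || !is.finite(beta)  || beta  <= 0) {
    stop("`alpha` and `beta` must be single positive finite numbers", call. = FALSE)
  }
  if (alpha < 1 || beta < 1) {
    warning("`alpha` and `beta` below 1 give bimodal/end-spiked threshold ",
            "distributions; values >= 1 (uniform or unimodal) are recommended",
            call. = FALSE)
  }
  if (!is.numeric(clamp_lo) || !is.numeric(clamp_hi) ||
      length(clamp_lo) != 1L || length(clamp_hi) != 1L ||
      clamp_lo <= 0 || clamp_hi >= 1 || clamp_lo >= clamp_hi) {
    stop("clamp bounds must satisfy 0 < clamp_lo < clamp_hi < 1", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, clamp_lo = clamp_lo, clamp_hi = clamp_hi),
    class = "beta_threshold_config"
  )
}

#' @export
print.beta_threshold_config <- function(x, ...) {
  cat(sprintf("Beta threshold config: alpha = %g, beta = %g, clamp [%g, %g]\n",
              x$alpha, x$beta, x$clamp_lo, x$clamp_hi))
  invisible(x)
}

#' Beta probability density of a threshold value
#'
#' Density \eqn{x^{\alpha-1}(1-x)^{\beta-1} / B(\alpha, \beta)} of the
#' threshold-sampling distribution, before clamping.
#'
#' @param x Numeric vector of values in \eqn{[0, 1]}.
#' @param cfg A [beta_threshold_config()].
#' @return Non-negative densities, same length as `x`.
#' @export
beta_pdf <- function(x, cfg) {
  stopifnot(inherits(cfg, "beta_threshold_config"))
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  stats::dbeta(x, cfg$alpha, cfg$beta)
}

#' Linear ramp-in schedule for selection thresholds
#'
#' Thresholds are introduced gradually: the sampled threshold is multiplied
#' by \eqn{\eta_n = \max(0, \min(1, (n - n_0)/\delta))}, so selection is
#' inactive (threshold 0, every unit kept) for the first `n0` steps and at
#' full strength from step `n0 + delta` onwards. The warm-up exploits the
#' tendency of neural networks to learn general patterns before memorizing
#' noisy labels.
#'
#' @param n0 Non-negative integer delay before the ramp starts.
#' @param delta Positive integer ramp length (number of steps from 0 to 1).
#' @param step_unit Whether `n` counts epochs (default) or mini-batches.
#' @return An object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(n0, delta, step_unit = c("epoch", "minibatch")) {
  step_unit <- match.arg(step_unit)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 0 || n0 != trunc(n0)) {
    stop("`n0` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta != trunc(delta)) {
    stop("`delta` must be a single positive integer", call. = FALSE)
  }
  structure(list(n0 = as.integer(n0), delta = as.integer(delta),
                 step_unit = step_unit),
            class = "threshold_schedule")
}

#' @export
print.threshold_schedule <- function(x, ...) {
  cat(sprintf("Threshold schedule: delay n0 = %d, ramp delta = %d %ss\n",
              x$n0, x$delta, x$step_unit))
  invisible(x)
}

#' Ramp multiplier at a given step
#'
#' @param n Integer step(s), `>= 0` (epochs or mini-batches per the
#'   schedule's `step_unit`).
#' @param sched A [threshold_schedule()].
#' @return `max(0, min(1, (n - n0)/delta))`, vectorized over `n`.
#' @export
schedule_factor <- function(n, sched) {
  stopifnot(inherits(sched, "threshold_schedule"))
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  pmax(0, pmin(1, (n - sched$n0) / sched$delta))
}

#' Draw clamped, ramp-scaled selection thresholds
#'
#' Draws `draws` thresholds from \eqn{Beta(\alpha, \beta)}, clamps each into
#' `[clamp_lo, clamp_hi]`, and multiplies by the ramp factor \eqn{\eta_n}.
#' Clamping precedes the ramp scaling so that during warm-up
#' (\eqn{\eta_n = 0}) the effective threshold is exactly 0 and every unit is
#' selected; a post-scaling clamp would reject low-posterior units even
#' before selection is meant to start.
#'
#' Uses R's global random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams beta_pdf
#' @param sched A [threshold_schedule()].
#' @param n Current step (epoch or mini-batch index).
#' @param draws Number of thresholds to draw.
#' @return Numeric vector of length `draws` in `[0, clamp_hi]`.
#' @export
sample_threshold <- function(cfg, sched, n, draws = 1L) {
  stopifnot(inherits(cfg, "beta_threshold_config"),
            inherits(sched, "threshold_schedule"))
  t <- stats::rbeta(draws, cfg$alpha, cfg$beta)
  t <- pmin(pmax(t, cfg$clamp_lo), cfg$clamp_hi)
  t * schedule_factor(n, sched)
}

#' Tiled per-pixel threshold field
#'
#' For dense (pixel-wise) selection a full-resolution field of independent
#' thresholds is wasteful; instead a coarse grid of thresholds is drawn and
#' each grid cell is expanded to a contiguous block of the target field
#' (nearest-neighbor tiling, grid cells filled in row-major order). Each
#' threshold is clamped and ramp-scaled as in [sample_threshold()].
#'
#' @inheritParams sample_threshold
#' @param grid_shape Integer `(rows, cols)` of the coarse threshold grid,
#'   e.g. `c(16, 16)`.
#' @param target_shape Integer `(H, W)` of the output field; each dimension
#'   must be at least the corresponding grid dimension.
#' @return An `H x W` numeric matrix with at most `rows * cols` distinct
#'   values.
#' @export
sample_threshold_map <- function(cfg, sched, n, grid_shape, target_shape) {
  stopifnot(length(grid_shape) == 2L, length(target_shape) == 2L)
  gr <- as.integer(grid_shape[1]); gc <- as.integer(grid_shape[2])
  h <- as.integer(target_shape[1]); w <- as.integer(target_shape[2])
  if (gr < 1L || gc < 1L) stop("grid dimensions must be >= 1", call. = FALSE)
  if (h < gr || w < gc) {
    stop("target dimensions must be at least the grid dimensions", call. = FALSE)
  }
  vals <- sample_threshold(cfg, sched, n, draws = gr * gc)
  grid <- matrix(vals, nrow = gr, ncol = gc, byrow = TRUE)  # row-major fill
  row_idx <- floor((seq_len(h) - 1L) * gr / h) + 1L
  col_idx <- floor((seq_len(w) - 1L) * gc / w) + 1L
  grid[row_idx, col_idx, drop = FALSE]
}
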