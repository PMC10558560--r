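# Label-noise transition matrices and reproducible label corruption.

#' Specify a label-noise model
#'
#' Two corruption families are supported. *Bias* (label-flipping) noise
#' mimics observer bias: a corrupted label is replaced by the label of the
#' neighboring class, here the cyclic successor `(i %% C) + 1`. *Uniform*
#' noise replaces a corrupted label with a uniformly chosen *other* label.
#' `kind = "none"` is the identity model.
#'
#' Bias noise at a rate of 0.5 or more would flip the majority of a class's
#' labels to the same wrong class, so the correct label would no longer be
#' the majority vote; such rates trigger a warning.
#'
#' @param kind One of `"bias"`, `"uniform"`, `"none"`.
#' @param rate Corruption rate in `[0, 1)`. Ignored for `kind = "none"`
#'   (forced to 0).
#' @param num_classes Number of classes `C >= 2`.
#' @return An object of class `noise_spec`.
#' @seealso [make_transition_matrix()], [corrupt_labels()]
#' @export
noise_spec <- function(kind = c("bias", "uniform", "none"), rate = 0,
                       num_classes) {
  kind <- match.arg(kind)
  if (!is.numeric(num_classes) || length(num_classes) != 1L ||
      num_classes < 2 || num_classes != trunc(num_classes)) {
    stop("`num_classes` must be a single integer >= 2", call. = FALSE)
  }
  if (kind == "none") rate <- 0
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stop("`rate` must be a single number in [0, 1)", call. = FALSE)
  }
  if (kind == "bias" && rate >= 0.5) {
    warning("bias noise at rate >= 0.5 flips the majority of each class to ",
            "the neighboring class; the correct label is no longer the majority",
            call. = FALSE)
  }
  structure(list(kind = kind, rate = rate, num_classes = as.integer(num_classes)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise spec: %s, rate %.3f, %d classes\n",
              x$kind, x$rate, x$num_classes))
  invisible(x)
}

#' Build the noise transition matrix
#'
#' Returns the row-stochastic `C x C` matrix `T` with `T[i, j]` the
#' probability that true class `i` is recorded as class `j`:
#' * bias: `1 - r` on the diagonal, `r` on the cyclic successor;
#' * uniform: `1 - r` on the diagonal, `r / (C - 1)` elsewhere;
#' * none: the identity.
#'
#' @param spec A [noise_spec()].
#' @return A `C x C` numeric matrix with rows summing to 1.
#' @export
make_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  C <- spec$num_classes
  r <- spec$rate
  tm <- switch(spec$kind,
    none = diag(C),
    bias = {
      m <- diag(1 - r, C)
      m[cbind(seq_len(C), seq_len(C) %% C + 1L)] <- r
      m
    },
    uniform = {
      m <- matrix(r / (C - 1), C, C)
      diag(m) <- 1 - r
      m
    }
  )
  dimnames(tm) <- list(true = seq_len(C), recorded = seq_len(C))
  tm
}

#' Corrupt labels according to a noise model
#'
#' With `exact = TRUE` (the default, for reproducible experiment
#' conditions), exactly `round(rate * n_c)` labels of each class `c` are
#' corrupted; the corrupted units are chosen at random and their new labels
#' are drawn from the off-diagonal part of the class's transition-matrix
#' row. With `exact = FALSE` each label is corrupted independently by a
#' draw from its full matrix row (so the corrupted fraction is binomial).
#' In both modes a corrupted label always differs from the clean one.
#'
#' Uses R's global random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param labels Integer vector of clean class labels in `1..C`.
#' @param spec A [noise_spec()].
#' @param exact Corrupt an exact per-class count (`TRUE`) or i.i.d. per
#'   label (`FALSE`).
#' @return A list with components `noisy` (integer labels) and `corrupted`
#'   (logical mask marking changed labels).
#' @export
corrupt_labels <- function(labels, spec, exact = TRUE) {
  stopifnot(inherits(spec, "noise_spec"))
  C <- spec$num_classes
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > C)) {
    stop("`labels` must lie in 1..num_classes", call. = FALSE)
  }
  n <- length(labels)
  noisy <- labels
  if (spec$kind == "none" || spec$rate == 0 || n == 0L) {
    return(list(noisy = noisy, corrupted = logical(n)))
  }
  r <- spec$rate
  if (exact) {
    for (cl in seq_len(C)) {
      idx <- which(labels == cl)
      k <- round(r * length(idx))
      if (k == 0L) next
      pick <- if (length(idx) == 1L) idx else sample(idx, k)
      noisy[pick] <- if (spec$kind == "bias") {
        cl %% C + 1L
      } else {
        others <- seq_len(C)[-cl]
        others[sample.int(C - 1L, k, replace = TRUE)]
      }
    }
  } else {
    hit <- stats::runif(n) < r
    if (any(hit)) {
      if (spec$kind == "bias") {
        noisy[hit] <- labels[hit] %% C + 1L
      } else {
        # uniform over the C-1 other classes: shift draws past the clean label
        d <- sample.int(C - 1L, sum(hit), replace = TRUE)
        noisy[hit] <- ifelse(d >= labels[hit], d + 1L, d)
      }
    }
  }
  list(noisy = noisy, corrupted = noisy != labels)
}
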