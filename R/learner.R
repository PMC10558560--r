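# Small reference learners: multilayer perceptrons trained with Adam,
# exposing the predict/update contract the co-teaching loop needs
# (per-unit posteriors; gradient update on an arbitrary subset of units).

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    # He initialization, suited to the ReLU hidden layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  zeros <- function(p) lapply(p, function(m) m * 0)
  list(W = W, b = b,
       mW = zeros(W), vW = zeros(W), mb = zeros(b), vb = zeros(b),
       t = 0L, sizes = sizes)
}

mlp_forward <- function(net, x) {
  nl <- length(net$W)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- acts[[l]] %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < nl) pmax(z, 0) else z  # ReLU hidden, linear out
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# one Adam step on the mean cross-entropy over the given rows
mlp_adam_step <- function(net, x, y, lr, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  n <- nrow(x)
  nl <- length(net$W)
  acts <- mlp_forward(net, x)
  p <- softmax_rows(acts[[nl + 1L]])
  delta <- p
  delta[cbind(seq_len(n), y)] <- delta[cbind(seq_len(n), y)] - 1
  delta <- delta / n
  net$t <- net$t + 1L
  c1 <- 1 - beta1^net$t; c2 <- 1 - beta2^net$t
  for (l in rev(seq_len(nl))) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
    }
    net$mW[[l]] <- beta1 * net$mW[[l]] + (1 - beta1) * gW
    net$vW[[l]] <- beta2 * net$vW[[l]] + (1 - beta2) * gW^2
    net$mb[[l]] <- beta1 * net$mb[[l]] + (1 - beta1) * gb
    net$vb[[l]] <- beta2 * net$vb[[l]] + (1 - beta2) * gb^2
    net$W[[l]] <- net$W[[l]] - lr * (net$mW[[l]] / c1) /
      (sqrt(net$vW[[l]] / c2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (net$mb[[l]] / c1) /
      (sqrt(net$vb[[l]] / c2) + eps)
  }
  net
}

#' Construct a small reference learner
#'
#' Desk-scale learners satisfying the co-teaching predict/update contract:
#' * `"mlp_classifier"` — one-hidden-layer perceptron (ReLU, softmax) for
#'   vector features;
#' * `"small_cnn"` — two-hidden-layer perceptron on flattened inputs, a
#'   stand-in for the small image CNNs used at full scale;
#' * `"small_unet"` — pixel-wise classifier over local multi-scale image
#'   features (intensity, 3x3 and 7x7 box means, normalized coordinates), a
#'   stand-in for an encoder-decoder segmentation network. Its posteriors
#'   and updates operate at pixel granularity.
#'
#' Learners with different seeds start from different weights and hence
#' different decision boundaries — the diversity co-teaching exploits.
#'
#' @param kind One of `"mlp_classifier"`, `"small_cnn"`, `"small_unet"`.
#' @param seed Integer seed for weight initialization.
#' @param d_in Number of input features (ignored for `"small_unet"`, whose
#'   feature extraction is fixed at 5 per pixel).
#' @param n_classes Number of output classes.
#' @param hidden Integer vector of hidden-layer widths; defaults per kind
#'   (32; c(64, 32); 16).
#' @return An object of class `stocot_learner`.
#' @seealso [predict_posteriors()], [learner_update()]
#' @export
make_learner <- function(kind, seed, d_in = NULL, n_classes, hidden = NULL) {
  if (!kind %in% c("mlp_classifier", "small_cnn", "small_unet")) {
    stop(sprintf("unsupported learner kind '%s'", kind), call. = FALSE)
  }
  if (kind == "small_unet") d_in <- 5L
  if (is.null(d_in)) stop("`d_in` is required", call. = FALSE)
  hidden <- switch(kind,
    mlp_classifier = if (is.null(hidden)) 32L else hidden,
    small_cnn      = if (is.null(hidden)) c(64L, 32L) else hidden,
    small_unet     = if (is.null(hidden)) 16L else hidden
  )
  net <- mlp_init(c(d_in, hidden, n_classes), seed)
  structure(list(kind = kind, net = net, n_classes = as.integer(n_classes),
                 seed = seed),
            class = c(if (kind == "small_unet") "pixel_learner",
                      "stocot_learner"))
}

#' @export
print.stocot_learner <- function(x, ...) {
  cat(sprintf("stocot learner '%s': layers %s, seed %d\n", x$kind,
              paste(x$net$sizes, collapse = "-"), x$seed))
  invisible(x)
}

#' Predict class posteriors
#'
#' @param learner A learner from [make_learner()].
#' @param x Feature matrix (rows = instances), or for pixel learners a
#'   single `H x W` image matrix.
#' @param ... Unused.
#' @return An `n x C` matrix of class posteriors (rows sum to 1); for pixel
#'   learners an `H x W x C` array.
#' @export
predict_posteriors <- function(learner, x, ...) {
  UseMethod("predict_posteriors")
}

#' @export
predict_posteriors.stocot_learner <- function(learner, x, ...) {
  x <- as.matrix(x)
  acts <- mlp_forward(learner$net, x)
  softmax_rows(acts[[length(acts)]])
}

#' @export
predict_posteriors.pixel_learner <- function(learner, x, ...) {
  x <- as.matrix(x)
  p <- predict_posteriors.stocot_learner(learner, pixel_features(x))
  array(p, dim = c(nrow(x), ncol(x), learner$n_classes))
}

#' Gradient update on a set of training units
#'
#' One Adam step on the mean cross-entropy over the supplied units.
#'
#' @inheritParams predict_posteriors
#' @param y Integer labels in `1..C`; for pixel learners an `H x W` label
#'   map.
#' @param keep Optional logical mask selecting the units to train on (for
#'   pixel learners, an `H x W` mask). Default: all units.
#' @param lr Learning rate.
#' @param ... Unused.
#' @return The updated learner.
#' @export
learner_update <- function(learner, x, y, keep = NULL, lr = 1e-3, ...) {
  UseMethod("learner_update")
}

#' @export
learner_update.stocot_learner <- function(learner, x, y, keep = NULL,
                                          lr = 1e-3, ...) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!is.null(keep)) {
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (length(y) == 0L) return(learner)
  learner$net <- mlp_adam_step(learner$net, x, y, lr)
  learner
}

#' @export
learner_update.pixel_learner <- function(learner, x, y, keep = NULL,
                                         lr = 1e-3, ...) {
  x <- as.matrix(x)
  feats <- pixel_features(x)
  yv <- as.integer(as.vector(y))
  kv <- if (is.null(keep)) rep(TRUE, length(yv)) else as.vector(keep)
  if (!any(kv)) return(learner)
  learner$net <- mlp_adam_step(learner$net, feats[kv, , drop = FALSE],
                               yv[kv], lr)
  learner
}

# cumsum-based box mean with clamped (replicated) borders
box_mean <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) %/% 2L
  cs <- matrix(0, h + 1L, w + 1L)
  cs[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  lo_r <- pmax(seq_len(h) - r, 1L); hi_r <- pmin(seq_len(h) + r, h)
  lo_c <- pmax(seq_len(w) - r, 1L); hi_c <- pmin(seq_len(w) + r, w)
  s <- cs[hi_r + 1L, hi_c + 1L, drop = FALSE] -
    cs[lo_r, hi_c + 1L, drop = FALSE] -
    cs[hi_r + 1L, lo_c, drop = FALSE] + cs[lo_r, lo_c, drop = FALSE]
  cnt <- outer(hi_r - lo_r + 1L, hi_c - lo_c + 1L)
  s / cnt
}

# per-pixel features: intensity, two box-mean scales, normalized coordinates
pixel_features <- function(img) {
  h <- nrow(img); w <- ncol(img)
  cbind(as.vector(img),
        as.vector(box_mean(img, 3L)),
        as.vector(box_mean(img, 7L)),
        rep((seq_len(h) - 0.5) / h, times = w),
        rep((seq_len(w) - 0.5) / w, each = h))
}
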