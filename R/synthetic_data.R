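# Synthetic desk-scale datasets with known clean labels: a
# ring-of-Gaussians classification task and cardiac-like segmentation
# images with controllable annotation corruption.

#' Specify a ring-of-Gaussians classification task
#'
#' `C` isotropic Gaussian classes whose centers are equally spaced on a
#' circle. The geometry makes "neighboring class" meaningful: class `i`'s
#' nearest neighbors in feature space are classes `i - 1` and `i + 1`
#' (cyclically), so cyclic-successor bias noise is the hardest confusion —
#' an honest desk-scale analogue of observer-bias label flipping.
#'
#' @param num_classes Number of classes `C >= 3`.
#' @param samples_per_class Samples drawn per class.
#' @param radius Radius of the circle of class centers.
#' @param sigma Within-class standard deviation (per axis).
#' @param seed Integer seed.
#' @return An object of class `ring_task_spec`.
#' @export
ring_task_spec <- function(num_classes = 6L, samples_per_class = 1000L,
                           radius = 1, sigma = 0.15, seed = 1L) {
  if (num_classes < 3L) stop("`num_classes` must be >= 3", call. = FALSE)
  if (samples_per_class < 1L || radius <= 0 || sigma <= 0) {
    stop("`samples_per_class`, `radius` and `sigma` must be positive",
         call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes),
                 samples_per_class = as.integer(samples_per_class),
                 radius = radius, sigma = sigma, seed = as.integer(seed)),
            class = "ring_task_spec")
}

#' Generate a ring-of-Gaussians dataset
#'
#' Deterministic given the spec's seed. The attribute
#' `"bayes_error_bound"` carries a closed-form upper bound on the
#' Bayes-optimal error from the two-neighbor union bound,
#' `2 * pnorm(-d / (2 * sigma))` with `d = 2 * radius * sin(pi / C)` the
#' distance between adjacent class centers.
#'
#' @param spec A [ring_task_spec()].
#' @return A list of class `ring_task`: `features` (`n x 2` matrix),
#'   `labels` (integer, `1..C`, exactly `samples_per_class` each), `spec`.
#' @export
make_ring_task <- function(spec) {
  stopifnot(inherits(spec, "ring_task_spec"))
  set.seed(spec$seed)
  C <- spec$num_classes
  m <- spec$samples_per_class
  ang <- 2 * pi * (seq_len(C) - 1L) / C
  centers <- cbind(spec$radius * cos(ang), spec$radius * sin(ang))
  labels <- rep(seq_len(C), each = m)
  features <- centers[labels, ] +
    matrix(stats::rnorm(2L * C * m, sd = spec$sigma), ncol = 2L)
  perm <- sample(C * m)  # shuffle so class blocks are interleaved
  out <- list(features = features[perm, , drop = FALSE],
              labels = labels[perm], spec = spec)
  d <- 2 * spec$radius * sin(pi / C)
  attr(out, "bayes_error_bound") <- 2 * stats::pnorm(-d / (2 * spec$sigma))
  class(out) <- "ring_task"
  out
}

#' @export
print.ring_task <- function(x, ...) {
  cat(sprintf(
    "Ring task: %d classes x %d samples, radius %g, sigma %g (seed %d)\n",
    x$spec$num_classes, x$spec$samples_per_class, x$spec$radius,
    x$spec$sigma, x$spec$seed))
  cat(sprintf("  Bayes error bound: %.2e\n", attr(x, "bayes_error_bound")))
  invisible(x)
}

#' Specify synthetic cardiac-like segmentation data
#'
#' Short-axis-like images built from simple geometry: a bright disc (blood
#' pool) surrounded by an annulus (myocardium) on a dark background, with
#' small darker blobs inside the disc (papillary muscles). Annotation
#' corruption mimics a common real annotation inconsistency: in a fraction
#' of images the papillary-muscle pixels are relabeled as blood pool.
#'
#' Class coding of the label maps: 1 background, 2 blood pool,
#' 3 myocardium, 4 papillary muscle.
#'
#' @param n_images Number of images.
#' @param size Image side length in pixels (square images).
#' @param disc_radius Length-2 range the blood-pool radius is drawn from.
#' @param annulus_thickness Myocardium thickness in pixels.
#' @param n_blobs Papillary blobs per image.
#' @param blob_radius Blob radius in pixels.
#' @param corrupt_frac Fraction of images whose papillary pixels are
#'   relabeled to blood pool (applied to exactly `round(corrupt_frac *
#'   n_images)` images).
#' @param noise_sd Additive Gaussian intensity noise.
#' @param seed Integer seed.
#' @return An object of class `synthetic_seg_spec`.
#' @export
synthetic_seg_spec <- function(n_images = 20L, size = 64L,
                               disc_radius = c(10, 16),
                               annulus_thickness = 5L, n_blobs = 2L,
                               blob_radius = 3L, corrupt_frac = 0.4,
                               noise_sd = 0.05, seed = 1L) {
  if (n_images < 1L || size < 16L) {
    stop("need `n_images` >= 1 and `size` >= 16", call. = FALSE)
  }
  if (corrupt_frac < 0 || corrupt_frac > 1) {
    stop("`corrupt_frac` must be in [0, 1]", call. = FALSE)
  }
  if (max(disc_radius) + annulus_thickness >= size / 2) {
    stop("disc plus annulus must fit inside the image", call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 disc_radius = disc_radius,
                 annulus_thickness = annulus_thickness,
                 n_blobs = as.integer(n_blobs), blob_radius = blob_radius,
                 corrupt_frac = corrupt_frac, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_seg_spec")
}

SEG_BACKGROUND <- 1L
SEG_BLOOD <- 2L
SEG_MYO <- 3L
SEG_PAPILLARY <- 4L

#' Generate synthetic segmentation images with annotation corruption
#'
#' Deterministic given the spec's seed. Corrupted label maps equal the
#' clean maps except that every papillary pixel is relabeled to blood pool
#' in exactly `round(corrupt_frac * n_images)` images (chosen at random);
#' `corrupted` flags which images were altered, so the corruption is
#' exactly reconstructable from the clean maps and the flags.
#'
#' @param spec A [synthetic_seg_spec()].
#' @return A list of class `synthetic_seg`: `images` (list of `size x
#'   size` intensity matrices in roughly `[0, 1]`), `clean_maps` and
#'   `noisy_maps` (lists of integer label maps), `corrupted` (logical
#'   vector), `spec`.
#' @export
make_synthetic_seg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_seg_spec"))
  set.seed(spec$seed)
  s <- spec$size
  xs <- matrix(rep(seq_len(s), times = s), s, s)  # row coordinate
  ys <- matrix(rep(seq_len(s), each = s), s, s)   # column coordinate
  intensity <- c(0.15, 0.85, 0.45, 0.40)  # bg, blood, myo, papillary
  images <- clean <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    cx <- s / 2 + stats::runif(1, -s / 16, s / 16)
    cy <- s / 2 + stats::runif(1, -s / 16, s / 16)
    rr <- stats::runif(1, spec$disc_radius[1], spec$disc_radius[2])
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    map <- matrix(SEG_BACKGROUND, s, s)
    map[d <= rr + spec$annulus_thickness] <- SEG_MYO
    map[d <= rr] <- SEG_BLOOD
    for (b in seq_len(spec$n_blobs)) {
      # blob center inside the disc, margin one blob radius
      br <- stats::runif(1, 0, max(rr - spec$blob_radius - 1, 1))
      ba <- stats::runif(1, 0, 2 * pi)
      bd <- sqrt((xs - (cx + br * cos(ba)))^2 + (ys - (cy + br * sin(ba)))^2)
      map[bd <= spec$blob_radius & map == SEG_BLOOD] <- SEG_PAPILLARY
    }
    img <- matrix(intensity[map], s, s) +
      matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
    images[[i]] <- img
    clean[[i]] <- map
  }
  n_corrupt <- round(spec$corrupt_frac * spec$n_images)
  corrupted <- logical(spec$n_images)
  corrupted[sample(spec$n_images, n_corrupt)] <- TRUE
  noisy <- clean
  for (i in which(corrupted)) {
    m <- noisy[[i]]
    m[m == SEG_PAPILLARY] <- SEG_BLOOD
    noisy[[i]] <- m
  }
  structure(list(images = images, clean_maps = clean, noisy_maps = noisy,
                 corrupted = corrupted, spec = spec),
            class = "synthetic_seg")
}

#' @export
print.synthetic_seg <- function(x, ...) {
  cat(sprintf(
    "Synthetic segmentation set: %d images of %dx%d, %d corrupted (seed %d)\n",
    x$spec$n_images, x$spec$size, x$spec$size, sum(x$corrupted),
    x$spec$seed))
  invisible(x)
}
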