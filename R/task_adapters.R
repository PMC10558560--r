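# Adapters mapping task families (single-label, multi-label, dense
# segmentation) onto the unit-batch abstraction.

#' Instance-level units from class posteriors
#'
#' For single-label classification each instance is one unit: its selection
#' statistic is the posterior assigned to its recorded label, and its loss
#' is the cross-entropy `-log` of that posterior.
#'
#' @param posteriors An `n x C` matrix of class posteriors; rows must sum
#'   to 1 (within numerical tolerance) with entries in `[0, 1]`.
#' @param labels Integer recorded labels in `1..C`.
#' @return A [unit_batch()] with `granularity = "instance"`.
#' @export
instance_units <- function(posteriors, labels) {
  posteriors <- as.matrix(posteriors)
  labels <- as.integer(labels)
  if (any(posteriors < 0 | posteriors > 1)) {
    stop("posteriors must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(posteriors) - 1) > 1e-6)) {
    stop("posterior rows must sum to 1", call. = FALSE)
  }
  if (length(labels) != nrow(posteriors) ||
      any(labels < 1L | labels > ncol(posteriors))) {
    stop("`labels` must be in 1..C with one entry per posterior row",
         call. = FALSE)
  }
  p <- posteriors[cbind(seq_along(labels), labels)]
  unit_batch(p, losses = -log(p), granularity = "instance")
}

#' Multi-label units from per-label probabilities
#'
#' Multi-label classification is selected at (instance, label) granularity:
#' unit `(i, l)` has posterior `p[i, l]` when the recorded label is positive
#' and `1 - p[i, l]` when it is negative, i.e. the probability the model
#' assigns to the *recorded* labeling. An instance with `L` labels
#' contributes `L` units.
#'
#' @param probs An `n x L` matrix of per-label positive-class
#'   probabilities in `[0, 1]`.
#' @param label_vectors An `n x L` binary (0/1) matrix of recorded labels.
#' @return A [unit_batch()] with `granularity = "instance_label"`; unit
#'   order is instance-major (instance 1's L labels first). The instance
#'   and label index of each unit are attached as attributes `instance`
#'   and `label`.
#' @export
multilabel_units <- function(probs, label_vectors) {
  probs <- as.matrix(probs)
  yv <- as.matrix(label_vectors)
  if (!all(dim(probs) == dim(yv))) {
    stop("`probs` and `label_vectors` must have the same shape", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("per-label probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(yv %in% c(0, 1))) {
    stop("`label_vectors` must be binary", call. = FALSE)
  }
  p <- ifelse(yv == 1, probs, 1 - probs)
  # instance-major flattening: rows vary slowest
  pt <- as.vector(t(p))
  out <- unit_batch(pt, losses = -log(pt), granularity = "instance_label")
  attr(out, "instance") <- rep(seq_len(nrow(p)), each = ncol(p))
  attr(out, "label") <- rep(seq_len(ncol(p)), times = nrow(p))
  out
}

#' Pixel-wise selection against a threshold field
#'
#' Dense segmentation selects or rejects individual pixels: pixel `(i, j)`
#' is kept iff its posterior for the recorded (reference) class at that
#' pixel is at least the local threshold `threshold_field[i, j]`. The
#' returned loss is the cross-entropy averaged over kept pixels only (`NA`
#' if every pixel is rejected).
#'
#' @param pred_probs An `H x W x C` array of per-pixel class posteriors.
#' @param label_map An `H x W` integer map of recorded labels in `1..C`.
#' @param threshold_field An `H x W` threshold matrix, typically from
#'   [sample_threshold_map()].
#' @return A list: `keep_mask` (`H x W` logical), `loss` (mean
#'   cross-entropy over kept pixels), `posteriors_true` (`H x W` matrix of
#'   recorded-label posteriors).
#' @export
pixel_units <- function(pred_probs, label_map, threshold_field) {
  d <- dim(pred_probs)
  if (length(d) != 3L) stop("`pred_probs` must be an H x W x C array",
                            call. = FALSE)
  if (is.null(dim(label_map)) || !all(dim(label_map) == d[1:2]) ||
      is.null(dim(threshold_field)) || !all(dim(threshold_field) == d[1:2])) {
    stop("`label_map` and `threshold_field` must both be H x W", call. = FALSE)
  }
  label_map <- matrix(as.integer(label_map), d[1], d[2])
  if (any(label_map < 1L | label_map > d[3])) {
    stop("labels must lie in 1..C", call. = FALSE)
  }
  idx <- cbind(rep(seq_len(d[1]), times = d[2]),
               rep(seq_len(d[2]), each = d[1]),
               as.vector(label_map))
  p_true <- matrix(pred_probs[idx], d[1], d[2])
  keep <- p_true >= threshold_field
  loss <- if (any(keep)) mean(-log(p_true[keep])) else NA_real_
  list(keep_mask = keep, loss = loss, posteriors_true = p_true)
}

#' Render a keep-mask as a monochrome image
#'
#' Selected pixels are white (1), rejected pixels black (0). Visualizing
#' the masks during training reveals where labels are noisy: rejected
#' regions coincide with mislabeled structures and ambiguous borders.
#'
#' @param keep_mask An `H x W` logical matrix.
#' @param file Optional path; if given and the \pkg{png} package is
#'   available, the image is written as a PNG.
#' @return Invisibly, the `H x W` numeric 0/1 image.
#' @export
selection_mask_render <- function(keep_mask, file = NULL) {
  img <- matrix(as.numeric(keep_mask), nrow(keep_mask), ncol(keep_mask))
  if (!is.null(file)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package", call. = FALSE)
    }
    png::writePNG(img, file)
  }
  invisible(img)
}
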