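# Segmentation evaluation metrics: Dice overlap and boundary distance
# metrics (symmetric Hausdorff and mean surface distance).

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks.
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of the same shape.
#' @return The Dice coefficient in `[0, 1]`; `NaN` if both masks are empty.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  check_mask_pair(mask_a, mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(NaN)
  2 * sum(a & b) / denom
}

check_mask_pair <- function(mask_a, mask_b) {
  if (!all(dim(as.matrix(mask_a)) == dim(as.matrix(mask_b)))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  invisible(TRUE)
}

# boundary pixels: foreground with at least one 4-neighbor outside the
# foreground (image border counts as outside)
mask_boundary <- function(mask) {
  m <- as.matrix(mask)
  fg <- m != 0
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(fg & !interior, arr.ind = TRUE)
}

# for each point in `from` (k x 2), distance to nearest point in `to`
min_dists <- function(from, to, spacing) {
  dr <- outer(from[, 1L] * spacing[1L], to[, 1L] * spacing[1L], "-")
  dc <- outer(from[, 2L] * spacing[2L], to[, 2L] * spacing[2L], "-")
  sqrt(apply(dr^2 + dc^2, 1L, min))
}

surface_points <- function(mask_a, mask_b) {
  check_mask_pair(mask_a, mask_b)
  pa <- mask_boundary(mask_a)
  pb <- mask_boundary(mask_b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("distance metrics require at least one foreground pixel per mask",
         call. = FALSE)
  }
  list(a = pa, b = pb)
}

#' Symmetric Hausdorff distance between mask surfaces
#'
#' The larger of the two directed Hausdorff distances between the boundary
#' point sets of the masks (4-connectivity boundaries), in physical units.
#'
#' @inheritParams dice
#' @param spacing Length-2 pixel spacing `(row, col)`, default `c(1, 1)`.
#' @return The Hausdorff distance (`>= 0`).
#' @export
hausdorff <- function(mask_a, mask_b, spacing = c(1, 1)) {
  p <- surface_points(mask_a, mask_b)
  max(max(min_dists(p$a, p$b, spacing)), max(min_dists(p$b, p$a, spacing)))
}

#' Symmetric mean surface distance between masks
#'
#' Average of the two directed mean boundary distances (each boundary
#' pixel's distance to the nearest boundary pixel of the other mask), in
#' physical units.
#'
#' @inheritParams hausdorff
#' @return The mean surface distance (`>= 0`).
#' @export
mean_surface_distance <- function(mask_a, mask_b, spacing = c(1, 1)) {
  p <- surface_points(mask_a, mask_b)
  (mean(min_dists(p$a, p$b, spacing)) + mean(min_dists(p$b, p$a, spacing))) / 2
}
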