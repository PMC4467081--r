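#' Watershed clump splitting (baseline)
#'
#' The classical marker-based splitter the peak method is compared
#' against: the Euclidean distance transform of the foreground is
#' computed, negated, and flooded from its regional minima (equivalently,
#' basins are grown from the regional maxima of the distance map). No
#' minima suppression is applied by default, which honestly reproduces
#' the method's tendency to fragment irregular clumps.
#'
#' @param labels A [label_map] of the preliminary masks.
#' @param h Basin depth tolerance (h-minima style suppression); `0`
#'   disables suppression. Default 0.
#' @param min_area_px Minimum basin area kept. Default 0 (keep all).
#' @return A relabeled [label_map] with one component per basin.
#' @export
watershed_split <- function(labels, h = 0, min_area_px = 0) {
  stopifnot(inherits(labels, "label_map"))
  binary <- labels$labels > 0L
  if (!any(binary)) return(label_map(matrix(0L, nrow(binary), ncol(binary))))
  d <- EBImage::distmap(EBImage::Image(binary * 1))
  w <- EBImage::watershed(d, tolerance = h)
  relabel_by_area(matrix(as.integer(w), nrow(binary), ncol(binary)), min_area_px)
}

#' Two-phase region-based active contour (baseline)
#'
#' Piecewise-constant two-phase segmentation (Chan-Vese model): a level
#' set is evolved so that the image is approximated by one mean inside
#' and one outside the zero level, with curve-length regularization
#' applied as Gaussian smoothing of the level-set function. A comparison
#' baseline only; like thresholding it is a global region criterion and
#' underestimates the faint outer rim of cells.
#'
#' @param image An [image2d] or matrix.
#' @param mu Length-regularization strength: sigma (px) of the smoothing
#'   applied to the level set each iteration. Default 1.
#' @param dt Explicit time step. Default 1.
#' @param max_iter Iteration cap. Default 200.
#' @param tol Stop when the foreground changes by fewer than `tol`
#'   pixels between iterations. Default 0.
#' @param min_area_px Minimum component area kept when labeling the
#'   foreground. Default 50.
#' @return A [label_map]; attribute `converged` is `FALSE` when the
#'   iteration cap was reached.
#' @export
region_acm_segment <- function(image, mu = 1, dt = 1, max_iter = 200,
                               tol = 0, min_area_px = 50) {
  mat <- as_image_matrix(image)
  phi <- mat - mean(mat)
  prev_fg <- -1L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    inside <- phi > 0
    n_in <- sum(inside)
    if (n_in == 0L || n_in == length(phi)) break
    c1 <- mean(mat[inside]); c2 <- mean(mat[!inside])
    force <- -(mat - c1)^2 + (mat - c2)^2
    phi <- phi + dt * force
    phi <- pmin(pmax(phi, -1), 1)  # keep the level set well scaled
    if (mu > 0) phi <- smooth_image(phi, mu)
    fg <- sum(phi > 0)
    if (abs(fg - prev_fg) <= tol && it > 1) { converged <- TRUE; break }
    prev_fg <- fg
  }
  out <- label_components(phi > 0, min_area_px = min_area_px)
  attr(out, "converged") <- converged
  out
}

#' Pure thresholding segmentation (baseline)
#'
#' Threshold, label, done: the "global approach" on its own, without the
#' contour expansion refinement.
#'
#' @param image An [image2d] or matrix.
#' @param spec A [threshold_spec].
#' @param min_area_px Minimum component area. Default 50.
#' @return A [label_map].
#' @export
threshold_segment <- function(image, spec, min_area_px = 50) {
  thr <- compute_threshold(image, spec)
  label_components(binarize(image, thr), min_area_px = min_area_px)
}
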