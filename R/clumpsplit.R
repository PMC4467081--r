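#' Partition a clump mask among its peaks
#'
#' Divides a multi-peak mask component into one subarea per peak: each
#' component pixel is assigned to the Euclidean-nearest peak (in px, with
#' ties broken by lowest peak index in detection order). If plain
#' Euclidean assignment leaves a subarea disconnected from its peak (a
#' bent clump), only the connected part containing the peak is kept and
#' orphaned pixels are reassigned by geodesic growth of the neighboring
#' subareas within the mask.
#'
#' @param mask Logical matrix, `TRUE` on the clump component.
#' @param peaks Data frame with 0-based `row`, `col` of the peaks inside
#'   the component (detection order defines the tie rule).
#' @param spacing_px Vertex spacing for the extracted subarea contours.
#' @return An object of class `clump_partition`: list with `assignment`
#'   (integer matrix, 0 outside the component, peak index inside) and
#'   `subcontours` (list of [cell_contour], one per peak).
#' @export
partition_mask <- function(mask, peaks, spacing_px = 2) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  k <- nrow(peaks)
  if (k < 1) cellseg_stop("cellseg_param_error", "need at least one peak")
  px <- which(mask, arr.ind = TRUE)
  if (k == 1L) {
    assignment <- matrix(0L, nrow(mask), ncol(mask))
    assignment[px] <- 1L
  } else {
    # squared Euclidean distance pixel centers (0-based) -> peaks
    d2 <- outer(px[, "row"] - 1, peaks$row, "-")^2 +
          outer(px[, "col"] - 1, peaks$col, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    assignment <- matrix(0L, nrow(mask), ncol(mask))
    assignment[px] <- nearest
    assignment <- reconnect_orphans(assignment, mask, peaks)
  }
  subcontours <- lapply(seq_len(k), function(i)
    extract_initial_contour(assignment == i, spacing_px))
  structure(list(assignment = assignment, subcontours = subcontours),
            class = "clump_partition")
}

# Keep, for each peak, only the connected part of its subarea containing
# the peak; grow the remaining subareas into orphaned pixels (iterative
# 8-neighbor dilation within the mask, a geodesic-distance surrogate).
reconnect_orphans <- function(assignment, mask, peaks) {
  k <- nrow(peaks)
  orphan <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(k)) {
    sub <- assignment == i
    lab <- bwlabel8(sub)
    seed <- lab[round(peaks$row[i]) + 1L, round(peaks$col[i]) + 1L]
    if (seed == 0L) seed <- lab[sub][1]  # peak centroid off-grid: keep largest part
    bad <- sub & lab != seed
    if (any(bad)) { orphan <- orphan | bad; assignment[bad] <- 0L }
  }
  while (any(orphan)) {
    grew <- FALSE
    idx <- which(orphan, arr.ind = TRUE)
    h <- nrow(mask); w <- ncol(mask)
    for (q in seq_len(nrow(idx))) {
      r <- idx[q, 1]; cc <- idx[q, 2]
      nb <- assignment[max(1, r - 1):min(h, r + 1), max(1, cc - 1):min(w, cc + 1)]
      nb <- nb[nb > 0L]
      if (length(nb)) {
        assignment[r, cc] <- min(nb)
        orphan[r, cc] <- FALSE
        grew <- TRUE
      }
    }
    if (!grew) {  # isolated orphan island: give it to the nearest peak
      idx <- which(orphan, arr.ind = TRUE)
      d2 <- outer(idx[, 1] - 1, peaks$row, "-")^2 +
            outer(idx[, 2] - 1, peaks$col, "-")^2
      assignment[idx] <- max.col(-d2, ties.method = "first")
      break
    }
  }
  assignment
}

#' Expand the contours of a partitioned clump
#'
#' Evolves each subarea contour independently with the contour-expansion
#' snake. Mild improper division at initialization is corrected during
#' expansion because the intensity valley between touching cells repels
#' the contour. Overlaps between expanded neighbors are resolved later,
#' at rasterization, by nearest peak.
#'
#' @param subcontours List of [cell_contour] from [partition_mask].
#' @param image An [image2d].
#' @param field A [gradient_field].
#' @param params A [snake_params].
#' @return List of evolution results (see [evolve_contour]).
#' @export
refine_clump <- function(subcontours, image, field, params = snake_params()) {
  lapply(seq_along(subcontours), function(i)
    evolve_contour(subcontours[[i]], image, field, params, cell_id = i))
}
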