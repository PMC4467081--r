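#' Segmentation configuration
#'
#' Bundles every knob of the full pipeline; the configuration is echoed
#' into the result so a run can be reproduced exactly (all tie-breaks are
#' deterministic and the pipeline uses no randomness).
#'
#' @param threshold A [threshold_spec]. Default: Otsu with zero offset.
#' @param sigma_px Smoothing sigma fed to [smooth_image]; the smoothed
#'   image is used for thresholding and peak detection. Default 3.
#' @param sigma_force_px Milder smoothing for the snake's gradient force
#'   field. Peak detection needs heavy smoothing to kill organelle
#'   pseudo-peaks, but the contour equilibrium sits at the foot of the
#'   smoothed gradient, so boundary accuracy degrades by roughly the
#'   smoothing radius; a light denoise keeps the force field usable
#'   under camera noise without biasing the boundary. Default 1.
#' @param min_area_px Minimum mask area kept (debris defense). Default 50.
#' @param snake A [snake_params].
#' @param keep_traces Keep per-cell convergence traces. Default `FALSE`.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(threshold = threshold_spec("otsu_offset"),
                       sigma_px = 3, sigma_force_px = 1, min_area_px = 50,
                       snake = snake_params(), keep_traces = FALSE) {
  stopifnot(inherits(threshold, "threshold_spec"),
            inherits(snake, "snake_params"))
  structure(list(threshold = threshold, sigma_px = sigma_px,
                 sigma_force_px = sigma_force_px,
                 min_area_px = min_area_px, snake = snake,
                 keep_traces = keep_traces),
            class = "seg_config")
}

#' Segment all cells in a field of view
#'
#' The full pipeline: smooth; compute the global threshold; binarize and
#' label 8-connected masks (holes filled, small components dropped);
#' detect intensity peaks inside the masks; masks with a single peak are
#' taken as isolated cells, masks with several peaks are partitioned by
#' nearest peak into per-cell subareas; every (sub)mask boundary seeds a
#' contour-expansion snake evolved on the smoothed intensity gradient;
#' the converged contours are rasterized into a label map, with
#' overlapping pixels resolved to the cell with the nearest peak.
#'
#' @param image An [image2d].
#' @param config A [seg_config].
#' @return An object of class `segmentation_result`: list with `cells`
#'   (list of cell records: `cell_id`, `contour`, `area_px`, `area_um2`,
#'   `centroid_rc`, `from_clump`, `peak_rc`, `converged`), `label_map`,
#'   `threshold`, `config`, and optional `traces`.
#' @export
segment_cells <- function(image, config = seg_config()) {
  stopifnot(inherits(image, "image2d"), inherits(config, "seg_config"))
  sm <- smooth_image(image, config$sigma_px)
  thr <- compute_threshold(sm, config$threshold)
  masks <- label_components(binarize(sm, thr), min_area_px = config$min_area_px)
  field <- gradient_field(smooth_image(image, config$sigma_force_px))
  empty <- list(cells = list(),
                label_map = label_map(matrix(0L, image$height_px, image$width_px)),
                threshold = thr, config = config, traces = NULL)
  class(empty) <- "segmentation_result"
  if (masks$n_components == 0L) return(empty)

  peaks <- detect_peaks(sm, masks, threshold = thr)
  counts <- suppressWarnings(classify_masks(masks, peaks))

  # per-cell seeds: (initial contour, peak, clump flag), masks processed
  # in label order (descending area)
  seeds <- list()
  for (lb in seq_len(masks$n_components)) {
    comp <- masks$labels == lb
    pk <- peaks[peaks$label == lb, , drop = FALSE]
    if (nrow(pk) <= 1L) {
      ctr <- extract_initial_contour(comp, config$snake$resample_spacing_px)
      if (nrow(pk) == 1L) prc <- c(pk$row, pk$col)
      else {  # no surviving peak: fall back to the mask centroid
        ij <- which(comp, arr.ind = TRUE)
        prc <- c(mean(ij[, 1]) - 1, mean(ij[, 2]) - 1)
      }
      seeds[[length(seeds) + 1L]] <- list(contour = ctr, peak_rc = prc,
                                          from_clump = FALSE, label = lb)
    } else {
      part <- partition_mask(comp, pk, config$snake$resample_spacing_px)
      for (i in seq_len(nrow(pk)))
        seeds[[length(seeds) + 1L]] <- list(contour = part$subcontours[[i]],
                                            peak_rc = c(pk$row[i], pk$col[i]),
                                            from_clump = TRUE, label = lb)
    }
  }

  results <- lapply(seq_along(seeds), function(i) {
    tryCatch(
      evolve_contour(seeds[[i]]$contour, image, field, config$snake,
                     cell_id = i),
      cellseg_degenerate_contour = function(e) NULL)
  })
  keep <- !vapply(results, is.null, logical(1))
  seeds <- seeds[keep]; results <- results[keep]
  if (length(seeds) == 0L) return(empty)

  # rasterize with nearest-peak overlap resolution
  H <- image$height_px; W <- image$width_px
  labgrid <- matrix(0L, H, W)
  peak_rc <- do.call(rbind, lapply(seeds, `[[`, "peak_rc"))
  for (i in seq_along(results)) {
    m <- rasterize_contour(results[[i]]$contour, H, W)
    idx <- which(m)
    if (!length(idx)) next
    taken <- labgrid[idx] != 0L
    labgrid[idx[!taken]] <- i
    if (any(taken)) {
      ij <- arrayInd(idx[taken], c(H, W))
      other <- labgrid[idx[taken]]
      d_new <- (ij[, 1] - 1 - peak_rc[i, 1])^2 + (ij[, 2] - 1 - peak_rc[i, 2])^2
      d_old <- (ij[, 1] - 1 - peak_rc[other, 1])^2 + (ij[, 2] - 1 - peak_rc[other, 2])^2
      win <- d_new < d_old  # ties stay with the earlier (lower-index) cell
      labgrid[idx[taken][win]] <- i
    }
  }

  # drop cells that lost every pixel, relabel contiguously
  present <- sort(unique(labgrid[labgrid > 0L]))
  remap <- integer(length(seeds)); remap[present] <- seq_along(present)
  labgrid <- matrix(c(0L, remap)[labgrid + 1L], H, W)
  cells <- lapply(seq_along(present), function(j) {
    i <- present[j]
    ar <- compute_area(results[[i]]$contour,
                       image$pixel_size_x_um, image$pixel_size_y_um)
    p <- unclass(results[[i]]$contour)
    list(cell_id = j,
         contour = results[[i]]$contour,
         area_px = ar$area_px, area_um2 = ar$area_um2,
         centroid_rc = c(mean(p[, 2]), mean(p[, 1])),
         from_clump = seeds[[i]]$from_clump,
         peak_rc = seeds[[i]]$peak_rc,
         converged = results[[i]]$converged)
  })
  out <- list(cells = cells,
              label_map = label_map(labgrid),
              threshold = thr, config = config,
              traces = if (config$keep_traces)
                lapply(results[present], `[[`, "trace") else NULL)
  class(out) <- "segmentation_result"
  out
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d cells (%d from clumps), threshold %.4f>\n",
              length(x$cells),
              sum(vapply(x$cells, `[[`, logical(1), "from_clump")),
              x$threshold))
  invisible(x)
}
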