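#' Write segmentation outputs to disk
#'
#' Emits the artifact's on-disk formats into `out_dir`:
#' * `labels.tif` - the label map as a 16-bit grayscale TIFF;
#' * `contours.csv` - columns `cell_id`, `vertex_index`, `x_px`, `y_px`
#'   (0-based subpixel coordinates);
#' * `cells.json` - per-cell records plus the full configuration echo;
#' * `overlay.png` - RGB rendering of the contours on the input image
#'   (written only when `image` is supplied).
#'
#' @param result A `segmentation_result` from [segment_cells].
#' @param out_dir Output directory (created if missing).
#' @param image Optional [image2d] for the overlay.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_results <- function(result, out_dir, image = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  if (length(result$cells) > 65535)
    cellseg_stop("cellseg_capacity_error",
                 "16-bit label TIFF cannot hold %d cells", length(result$cells))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(labels = file.path(out_dir, "labels.tif"),
             contours = file.path(out_dir, "contours.csv"),
             cells = file.path(out_dir, "cells.json"))
  write_label_tiff(result$label_map, paths["labels"])

  rows <- lapply(result$cells, function(cl) {
    p <- unclass(cl$contour)
    data.frame(cell_id = cl$cell_id, vertex_index = seq_len(nrow(p)) - 1L,
               x_px = p[, 1], y_px = p[, 2])
  })
  ctab <- if (length(rows)) do.call(rbind, rows)
          else data.frame(cell_id = integer(0), vertex_index = integer(0),
                          x_px = numeric(0), y_px = numeric(0))
  write.csv(ctab, paths["contours"], row.names = FALSE)

  recs <- lapply(result$cells, function(cl)
    list(cell_id = cl$cell_id, area_px = cl$area_px, area_um2 = cl$area_um2,
         centroid_rc = cl$centroid_rc, from_clump = cl$from_clump,
         peak_rc = cl$peak_rc, converged = cl$converged))
  jsonlite::write_json(
    list(n_cells = length(result$cells), threshold = result$threshold,
         config = config_echo(result$config), cells = recs),
    paths["cells"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(image)) {
    paths <- c(paths, overlay = file.path(out_dir, "overlay.png"))
    write_overlay_png(result, image, paths["overlay"])
  }
  invisible(paths)
}

config_echo <- function(config) {
  list(threshold = unclass(config$threshold),
       sigma_px = config$sigma_px,
       sigma_force_px = config$sigma_force_px,
       min_area_px = config$min_area_px,
       snake = unclass(config$snake))
}

#' Write a label map as a 16-bit TIFF
#' @param labels A [label_map].
#' @param path Output path.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (labels$n_components > 65535)
    cellseg_stop("cellseg_capacity_error", "more than 65535 labels")
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read back a label map written by [write_label_tiff]
#' @param path Path to a 16-bit label TIFF.
#' @return A [label_map].
#' @export
read_label_tiff <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  label_map(matrix(as.integer(round(raw)), nrow(raw), ncol(raw)))
}

# Contours burned in red over the grayscale input.
write_overlay_png <- function(result, image, path) {
  g <- image$data
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  for (cl in result$cells) {
    p <- unclass(cl$contour)
    # dense sampling along edges so the drawn outline is continuous
    closed <- rbind(p, p[1, ])
    seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
    tt <- seq(0, sum(seg), by = 0.5)
    s <- c(0, cumsum(seg))
    xs <- approx(s, closed[, 1], xout = tt)$y
    ys <- approx(s, closed[, 2], xout = tt)$y
    i <- pmin(pmax(round(ys) + 1, 1), nrow(g))
    j <- pmin(pmax(round(xs) + 1, 1), ncol(g))
    rgb[cbind(i, j, 1)] <- 1
    rgb[cbind(i, j, 2)] <- 0
    rgb[cbind(i, j, 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
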