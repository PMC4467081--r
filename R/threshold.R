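#' Threshold specification
#'
#' Describes how the global threshold separating cell foreground from
#' background is chosen. Three methods are supported:
#' * `mean_offset`: mean image intensity plus an offset;
#' * `otsu_offset`: Otsu's threshold (between-class variance maximization
#'   on a 256-bin histogram) plus an offset;
#' * `absolute`: a fixed threshold value.
#'
#' Thresholds and offsets are on the normalized \[0, 1\] intensity scale;
#' 8-bit values such as 45 convert as `45 / 255`.
#'
#' @param method One of `"mean_offset"`, `"otsu_offset"`, `"absolute"`.
#' @param offset Offset added to the mean or Otsu threshold.
#' @param absolute_value Threshold in \[0, 1\] for the `absolute` method.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("mean_offset", "otsu_offset", "absolute"),
                           offset = 0, absolute_value = NULL) {
  method <- match.arg(method)
  if (method == "absolute") {
    if (is.null(absolute_value) || absolute_value < 0 || absolute_value > 1)
      cellseg_stop("cellseg_param_error",
                   "absolute thresholding requires absolute_value in [0, 1]")
  }
  structure(list(method = method, offset = offset,
                 absolute_value = absolute_value),
            class = "threshold_spec")
}

#' Compute the global threshold
#'
#' @param image An [image2d] or numeric matrix.
#' @param spec A [threshold_spec].
#' @return A single threshold in \[0, 1\] (clipped; a warning is issued if
#'   the pre-clip value fell outside).
#' @export
compute_threshold <- function(image, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  mat <- as_image_matrix(image)
  t0 <- switch(spec$method,
    mean_offset = mean(mat) + spec$offset,
    otsu_offset = otsu_threshold(mat) + spec$offset,
    absolute    = spec$absolute_value)
  if (t0 < 0 || t0 > 1)
    warning(sprintf("threshold %.4f outside [0, 1]; clipping", t0))
  min(max(t0, 0), 1)
}

# Otsu's method on a 256-bin histogram of [0, 1] intensities.
otsu_threshold <- function(mat) {
  as.numeric(EBImage::otsu(EBImage::Image(mat), range = c(0, 1), levels = 256))
}

#' Binarize an image
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.
#'
#' @param image An [image2d] or numeric matrix.
#' @param threshold Threshold in \[0, 1\].
#' @return A logical matrix.
#' @export
binarize <- function(image, threshold) {
  if (threshold < 0 || threshold > 1)
    cellseg_stop("cellseg_param_error", "threshold must be in [0, 1]")
  as_image_matrix(image) > threshold
}

#' Label map
#'
#' Integer grid with 0 for background and k >= 1 for the k-th component
#' (or cell). Components are 8-connected.
#'
#' @param labels Integer matrix.
#' @return An object of class `label_map` with fields `labels` and
#'   `n_components`.
#' @export
label_map <- function(labels) {
  storage.mode(labels) <- "integer"
  n <- max(0L, max(labels))
  present <- sort(unique(labels[labels > 0L]))
  if (n > 0L && !identical(present, seq_len(n)))
    cellseg_stop("cellseg_format_error", "labels must be contiguous 1..n")
  structure(list(labels = labels, n_components = n), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %d x %d px, %d components>\n",
              nrow(x$labels), ncol(x$labels), x$n_components))
  invisible(x)
}

#' Connected-component labeling of a binary mask
#'
#' Labels 8-connected foreground components, discards components smaller
#' than `min_area_px`, optionally fills interior holes (the snake needs a
#' single outer boundary per mask), and orders labels by descending area
#' with ties broken by the first pixel in row-major (top-left-most) order.
#'
#' @param binary Logical matrix (foreground = `TRUE`).
#' @param min_area_px Minimum component area in px; smaller components are
#'   dropped (debris defense). `0` disables. Default 50.
#' @param fill_holes Fill holes inside each component. Default `TRUE`.
#' @return A [label_map].
#' @export
label_components <- function(binary, min_area_px = 50, fill_holes = TRUE) {
  if (min_area_px < 0)
    cellseg_stop("cellseg_param_error", "min_area_px must be >= 0")
  stopifnot(is.matrix(binary))
  mode(binary) <- "logical"
  lab <- bwlabel8(binary)
  if (fill_holes && max(lab) > 0L)
    lab <- matrix(as.integer(EBImage::fillHull(lab)), nrow(lab), ncol(lab))
  relabel_by_area(lab, min_area_px)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels whose
# pixels touch diagonally are merged with a union-find pass.
bwlabel8 <- function(binary) {
  lab <- matrix(as.integer(EBImage::bwlabel(binary)), nrow(binary), ncol(binary))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  map <- c(0L, match(root, sort(unique(root))))
  matrix(map[lab + 1L], h, w)
}

# Area filter + deterministic relabeling (descending area, ties by first
# pixel in row-major order on the 0-based grid, i.e. by row then column).
relabel_by_area <- function(lab, min_area_px) {
  n <- max(lab)
  if (n == 0L) return(label_map(lab))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) return(label_map(matrix(0L, nrow(lab), ncol(lab))))
  # row-major scan order: transpose so R's column-major scan walks rows
  tl <- t(lab)
  idx <- which(tl > 0L)
  v <- tl[idx]
  first_rm <- integer(n)
  firsts <- !duplicated(v)
  first_rm[v[firsts]] <- idx[firsts]
  ord <- keep[order(-areas[keep], first_rm[keep])]
  map <- integer(n + 1L)
  map[ord + 1L] <- seq_along(ord)
  label_map(matrix(map[lab + 1L], nrow(lab), ncol(lab)))
}
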