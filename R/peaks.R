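#' Regional maxima of an intensity grid
#'
#' A regional maximum is an 8-connected plateau of equal intensity all of
#' whose outside neighbors are strictly lower. Each plateau contributes a
#' single peak at its centroid. Used on the smoothed image to locate
#' cells by the apex of their intensity dome.
#'
#' @param mat Numeric matrix.
#' @param mask Optional logical matrix restricting the search.
#' @return Data frame with 0-based `row`, `col` (plateau centroid) and
#'   `value` columns, in row-major detection order.
#' @export
regional_maxima <- function(mat, mask = NULL) {
  h <- nrow(mat); w <- ncol(mat)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mat
  nmax <- matrix(-Inf, h, w)
  neq <- matrix(FALSE, h, w)  # any 8-neighbor with equal value
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- pad[2:(h + 1) + dr, 2:(w + 1) + dc]
    nmax <- pmax(nmax, sh)
    neq <- neq | (sh == mat)
  }
  cand <- mat >= nmax
  if (!is.null(mask)) cand <- cand & mask
  if (!any(cand)) {
    return(data.frame(row = numeric(0), col = numeric(0), value = numeric(0)))
  }
  lab <- bwlabel8(cand)
  peaks <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    v <- mat[px[1, "row"], px[1, "col"]]
    # expand candidate component to its full equal-value plateau; if any
    # plateau pixel has a strictly greater neighbor somewhere, the set is
    # a shoulder, not a regional maximum
    if (any(neq[px])) {
      plateau <- flood_equal(mat, px, v)
      if (any(mat[cbind(pmin(pmax(rep(plateau[, 1], 9) + rep(-1:1, each = 3 * nrow(plateau)), 1), h),
                        pmin(pmax(rep(plateau[, 2], 9) + rep(rep(-1:1, each = nrow(plateau)), 3), 1), w))] > v))
        next
      px <- plateau
      if (!is.null(mask) && !all(mask[px])) next
    }
    peaks[[length(peaks) + 1L]] <-
      c(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1, value = v)
  }
  if (length(peaks) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0), value = numeric(0)))
  out <- as.data.frame(do.call(rbind, peaks))
  # deterministic row-major order of the plateau centroids
  out[order(out$row, out$col), , drop = FALSE]
}

# BFS flood over the 8-connected plateau of value v containing seed
# pixels. Plateaus are small in smoothed images; plain queue suffices.
flood_equal <- function(mat, seed, v) {
  h <- nrow(mat); w <- ncol(mat)
  seen <- matrix(FALSE, h, w)
  seen[seed] <- TRUE
  queue <- split(seed, row(seed))
  acc <- list(seed)
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; cc <- p[2] + dc
      if (r < 1 || r > h || cc < 1 || cc > w) next
      if (!seen[r, cc] && mat[r, cc] == v) {
        seen[r, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, cc)
        acc[[length(acc) + 1L]] <- matrix(c(r, cc), 1)
      }
    }
  }
  do.call(rbind, acc)
}

#' Detect cell marker peaks inside foreground masks
#'
#' Finds regional maxima of the smoothed intensity restricted to the
#' foreground of a label map, discarding maxima whose intensity is below
#' the binarization threshold. The peak count inside a mask determines
#' whether it holds one cell or a clump.
#'
#' @param smoothed Smoothed [image2d] (see [smooth_image]).
#' @param labels A [label_map] from [label_components].
#' @param threshold Binarization threshold; maxima below it are dropped.
#' @return An object of class `peak_set`: data frame with 0-based `row`,
#'   `col`, `value` and the containing component `label`, plus attribute
#'   `smoothing_sigma_px` when available.
#' @export
detect_peaks <- function(smoothed, labels, threshold = 0) {
  mat <- as_image_matrix(smoothed)
  stopifnot(inherits(labels, "label_map"))
  pk <- regional_maxima(mat, mask = labels$labels > 0L)
  pk <- pk[pk$value >= threshold, , drop = FALSE]
  lab <- if (nrow(pk)) labels$labels[cbind(round(pk$row) + 1L, round(pk$col) + 1L)]
         else integer(0)
  pk$label <- as.integer(lab)
  pk <- pk[pk$label > 0L, , drop = FALSE]
  rownames(pk) <- NULL
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Count peaks per mask
#'
#' Maps every component label to the number of detected peaks inside it.
#' A component with no surviving peak is kept as a single cell (count
#' coerced to 1) with a warning, matching the degenerate-case policy of
#' the splitter.
#'
#' @param labels A [label_map].
#' @param peaks A `peak_set` from [detect_peaks].
#' @return Integer vector of length `n_components`; names are labels.
#' @export
classify_masks <- function(labels, peaks) {
  stopifnot(inherits(labels, "label_map"))
  n <- labels$n_components
  counts <- integer(n)
  if (nrow(peaks)) {
    tb <- table(factor(peaks$label, levels = seq_len(n)))
    counts <- as.integer(tb)
  }
  if (any(counts == 0L) && n > 0L) {
    warning(sprintf("%d mask(s) without a detected peak kept as single cells",
                    sum(counts == 0L)))
    counts[counts == 0L] <- 1L
  }
  names(counts) <- seq_len(n)
  counts
}
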