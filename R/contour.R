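#' Closed contours
#'
#' A contour is an N x 2 numeric matrix of subpixel vertices with columns
#' `x` (along image columns) and `y` (along rows), in 0-based pixel-center
#' coordinates. The polygon is implicitly closed (the first vertex is not
#' repeated) and oriented so that its shoelace signed area is positive.
#'
#' @param points N x 2 numeric matrix of (x, y) vertices, N >= 8.
#' @return An object of class `cell_contour`.
#' @export
cell_contour <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 8)
    cellseg_stop("cellseg_geometry_error",
                 "a contour needs an N x 2 matrix with N >= 8 (got %d points)",
                 nrow(points))
  colnames(points) <- c("x", "y")
  if (signed_area(points) < 0) points <- points[nrow(points):1, , drop = FALSE]
  structure(points, class = c("cell_contour", "matrix"))
}

# Shoelace signed area; positive defines the package's canonical
# orientation (counterclockwise in mathematical axes).
signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Polygon area by the shoelace formula
#'
#' @param contour A `cell_contour` or N x 2 vertex matrix.
#' @param pixel_size_x_um,pixel_size_y_um Pixel sizes used to convert the
#'   pixel-square area to um^2.
#' @return List with `area_px` and `area_um2`.
#' @export
compute_area <- function(contour,
                         pixel_size_x_um = DEFAULT_PIXEL_SIZE_X,
                         pixel_size_y_um = DEFAULT_PIXEL_SIZE_Y) {
  p <- unclass(contour)
  if (is_self_intersecting(p))
    cellseg_stop("cellseg_geometry_error", "polygon is self-intersecting")
  a <- signed_area(p)
  if (a < 0) a <- -a  # CW input: auto-reorient for measurement
  list(area_px = a, area_um2 = a * pixel_size_x_um * pixel_size_y_um)
}

# Segment-intersection test over all non-adjacent edge pairs. O(N^2) but
# contours have at most a few hundred vertices.
is_self_intersecting <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]  # skip edges adjacent to edge i
    if (length(j) == 0) next
    d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
    d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
    d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
    d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Extract the outer boundary of a mask component as an initial contour
#'
#' Traces the 0.5-isocontour of the binary component (marching squares),
#' keeps the outermost ring, and resamples it to uniform arc-length
#' spacing. The result seeds the contour-expansion snake; because the
#' mask comes from thresholding it lies inside the true cell boundary.
#'
#' @param mask Logical matrix, `TRUE` on the component (holes filled).
#' @param spacing_px Target vertex spacing after resampling. Default 2.
#' @return A [cell_contour].
#' @export
extract_initial_contour <- function(mask, spacing_px = 2) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (!any(mask))
    cellseg_stop("cellseg_geometry_error", "empty mask has no boundary")
  h <- nrow(mask); w <- ncol(mask)
  border <- any(mask[1, ]) || any(mask[h, ]) || any(mask[, 1]) || any(mask[, w])
  # pad with a background ring so border-touching components still close;
  # the traced contour is then clipped back to the image bounds
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- mask * 1
  cl <- contourLines(x = 0:(h + 1) - 1, y = 0:(w + 1) - 1, z = z, levels = 0.5)
  if (length(cl) == 0)
    cellseg_stop("cellseg_geometry_error", "no boundary found")
  # z's first index runs over rows (y), second over columns (x)
  areas <- vapply(cl, function(cc) abs(signed_area(cbind(cc$y, cc$x))), numeric(1))
  cc <- cl[[which.max(areas)]]
  pts <- cbind(x = cc$y, y = cc$x)
  if (all(pts[nrow(pts), ] == pts[1, ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (border) {
    pts[, 1] <- pmin(pmax(pts[, 1], 0), w - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), h - 1)
  }
  cell_contour(resample_closed(pts, spacing_px))
}

# Uniform arc-length resampling of a closed polygon. Vertex count is
# max(8, round(L / spacing)).
resample_closed <- function(p, spacing_px) {
  p <- as.matrix(p)
  closed <- rbind(p, p[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  keep <- c(TRUE, seg > 1e-12)  # drop duplicated vertices
  closed <- closed[keep, , drop = FALSE]
  if (nrow(closed) < 4)
    cellseg_stop("cellseg_geometry_error", "degenerate contour")
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- max(8L, as.integer(round(L / spacing_px)))
  ti <- seq(0, L, length.out = n + 1)[-(n + 1)]
  cbind(x = approx(s, closed[, 1], xout = ti)$y,
        y = approx(s, closed[, 2], xout = ti)$y)
}

#' Contour perimeter
#' @param contour A `cell_contour` or N x 2 matrix.
#' @return Perimeter in px.
#' @export
contour_length <- function(contour) {
  p <- as.matrix(unclass(contour))
  closed <- rbind(p, p[1, ])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

#' Rasterize a closed contour to a pixel mask
#'
#' A pixel belongs to the polygon iff its center (0-based integer
#' coordinates) is inside under the even-odd rule.
#'
#' @param contour A `cell_contour` or N x 2 matrix.
#' @param height_px,width_px Output grid size.
#' @return Logical matrix.
#' @export
rasterize_contour <- function(contour, height_px, width_px) {
  p <- as.matrix(unclass(contour))
  out <- matrix(FALSE, height_px, width_px)
  xmin <- max(0L, as.integer(floor(min(p[, 1]))))
  xmax <- min(width_px - 1L, as.integer(ceiling(max(p[, 1]))))
  ymin <- max(0L, as.integer(floor(min(p[, 2]))))
  ymax <- min(height_px - 1L, as.integer(ceiling(max(p[, 2]))))
  if (xmax < xmin || ymax < ymin) return(out)
  gx <- rep(xmin:xmax, times = ymax - ymin + 1)
  gy <- rep(ymin:ymax, each = xmax - xmin + 1)
  inside <- points_in_polygon(gx, gy, p)
  out[cbind(gy + 1L, gx + 1L)[inside, , drop = FALSE]] <- TRUE
  out
}

# Even-odd (crossing number) point-in-polygon test, vectorized over
# query points.
points_in_polygon <- function(qx, qy, p) {
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(qx))
  for (e in seq_len(n)) {
    crosses <- (y1[e] > qy) != (y2[e] > qy)
    if (any(crosses)) {
      xin <- x1[e] + (qy[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      idx <- which(crosses)[qx[crosses] < xin]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}
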