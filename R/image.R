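#' Single-channel intensity image
#'
#' An `image2d` is the package's in-memory image container: a numeric
#' matrix of intensities normalized to \[0, 1\], indexed `[row, col]` with
#' rows running down the image (y) and columns running right (x), plus the
#' physical pixel size in micrometres. All user-facing pixel coordinates
#' are 0-based: pixel `[i, j]` (1-based matrix indices) has its center at
#' `(x, y) = (j - 1, i - 1)`.
#'
#' @param data Numeric matrix of intensities in \[0, 1\].
#' @param pixel_size_x_um,pixel_size_y_um Pixel size in um/px. Defaults
#'   correspond to a 1344 x 1024 frame imaging a 900 um x 686 um field of
#'   view (approximately 0.67 um/px).
#' @param source_dtype One of `"uint8"`, `"uint16"`, `"float"`; records the
#'   on-disk sample type the data were normalized from.
#' @return An object of class `image2d`.
#' @export
image2d <- function(data,
                    pixel_size_x_um = DEFAULT_PIXEL_SIZE_X,
                    pixel_size_y_um = DEFAULT_PIXEL_SIZE_Y,
                    source_dtype = "float") {
  if (!is.matrix(data) || !is.numeric(data))
    cellseg_stop("cellseg_format_error", "image data must be a numeric matrix")
  if (nrow(data) < 8 || ncol(data) < 8)
    cellseg_stop("cellseg_format_error",
                 "image must be at least 8 x 8 px, got %d x %d",
                 nrow(data), ncol(data))
  if (anyNA(data) || min(data) < 0 || max(data) > 1)
    cellseg_stop("cellseg_format_error", "intensities must lie in [0, 1]")
  if (pixel_size_x_um <= 0 || pixel_size_y_um <= 0)
    cellseg_stop("cellseg_format_error", "pixel sizes must be positive")
  structure(
    list(data = data,
         height_px = nrow(data), width_px = ncol(data),
         pixel_size_x_um = pixel_size_x_um,
         pixel_size_y_um = pixel_size_y_um,
         source_dtype = source_dtype),
    class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d px (%.3f x %.3f um/px), source %s>\n",
              x$height_px, x$width_px,
              x$pixel_size_x_um, x$pixel_size_y_um, x$source_dtype))
  invisible(x)
}

as_image_matrix <- function(image) {
  if (inherits(image, "image2d")) image$data
  else if (is.matrix(image)) image
  else cellseg_stop("cellseg_format_error", "expected an image2d or a matrix")
}

#' Read a grayscale microscopy image
#'
#' Reads an 8/16-bit integer or float grayscale TIFF or PNG and normalizes
#' intensities to \[0, 1\] by dividing by the dtype maximum (255 or 65535);
#' float inputs are clipped to \[0, 1\].
#'
#' @param path Path to a grayscale TIFF or PNG file.
#' @param pixel_size_x_um,pixel_size_y_um Pixel size overrides (um/px);
#'   defaults assume the 900/1344 and 686/1024 um/px field-of-view scaling.
#' @return An [image2d].
#' @export
read_image <- function(path,
                       pixel_size_x_um = DEFAULT_PIXEL_SIZE_X,
                       pixel_size_y_um = DEFAULT_PIXEL_SIZE_Y) {
  if (!file.exists(path))
    cellseg_stop("cellseg_io_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e)
                      cellseg_stop("cellseg_io_error", "unreadable TIFF: %s", conditionMessage(e)))
    if (length(dim(raw)) == 3L)
      cellseg_stop("cellseg_format_error",
                   "expected single-channel image, got %d channels", dim(raw)[3])
    if (max(raw) <= 1 && !all(raw == floor(raw))) {
      dtype <- "float"
      data <- pmin(pmax(raw, 0), 1)
    } else if (max(raw) > 255) {
      dtype <- "uint16"; data <- raw / 65535
    } else {
      # readTIFF(as.is) yields integers for integer samples; floats <= 1
      # that are all integral (0/1 masks) are treated as 8-bit.
      dtype <- if (all(raw == floor(raw))) "uint8" else "float"
      data <- if (dtype == "uint8") raw / 255 else pmin(pmax(raw, 0), 1)
    }
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e)
                      cellseg_stop("cellseg_io_error", "unreadable PNG: %s", conditionMessage(e)))
    if (length(dim(raw)) == 3L)
      cellseg_stop("cellseg_format_error",
                   "expected single-channel image, got %d channels", dim(raw)[3])
    # readPNG already normalizes by the sample maximum
    dtype <- if (all(abs(raw * 255 - round(raw * 255)) < 1e-9)) "uint8" else "uint16"
    data <- pmin(pmax(raw, 0), 1)
  } else {
    cellseg_stop("cellseg_format_error", "unsupported image format: .%s", ext)
  }
  storage.mode(data) <- "double"
  image2d(data, pixel_size_x_um, pixel_size_y_um, source_dtype = dtype)
}

#' Bilinear interpolation on a pixel grid
#'
#' Samples a matrix at subpixel positions given in 0-based pixel-center
#' coordinates (`x` along columns, `y` along rows). Positions outside the
#' grid are clamped to the nearest border pixel.
#'
#' @param mat Numeric matrix.
#' @param x,y Numeric vectors of equal length, 0-based coordinates.
#' @return Numeric vector of interpolated values.
#' @export
bilinear_interp <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L
  v00 <- mat[cbind(i, j)];      v01 <- mat[cbind(i, j + 1L)]
  v10 <- mat[cbind(i + 1L, j)]; v11 <- mat[cbind(i + 1L, j + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
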