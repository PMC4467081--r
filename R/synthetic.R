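#' Synthetic scene specification
#'
#' Describes a negative phase contrast phantom: transparent cells of
#' given dome-shaped height profiles in a medium, rendered through the
#' linear phase-shift/intensity model. In negative phase contrast,
#' optically denser objects (refractive index `n2` > medium `n1`) appear
#' brighter than background, with intensity approximately linear in
#' height: the phase shift is `dphi = 2*pi*(n2 - n1)*h/lambda` and the
#' intensity `I = 1 + 2*dphi` before display scaling.
#'
#' @param cells Data frame with one row per cell: `center_row`,
#'   `center_col` (0-based px), `a_px`, `b_px` (semi-axes), `theta_rad`
#'   (orientation), `height_um` (apex height), `profile`
#'   (`"cosine_dome"` or `"gaussian_dome"`).
#' @param height_px,width_px Frame size. Defaults 1024 x 1344.
#' @param n1,n2 Refractive indices of medium and cell (`n2 > n1`).
#'   Defaults 1.335 / 1.365 (cytoplasm about 0.03 above culture medium).
#' @param lambda_um Illumination wavelength, default 0.55 um.
#' @param background_level Background intensity in \[0, 1\], default 0.15.
#' @param intensity_scale Display gain applied to `I - 1`; the default
#'   0.165 puts a 4 um apex near intensity 0.6.
#' @param noise_sigma Additive Gaussian noise sd, default 0.01.
#' @param speckles List `(count_per_cell, amplitude, radius_px)`: bright
#'   organelle-like bumps placed inside cells (pseudo-peak sources).
#'   Default: none.
#' @param debris List `(count, radius_px, level)`: cell-free bright
#'   blobs. Default: none.
#' @param seed Integer seed making the realization deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(cells,
                       height_px = 1024, width_px = 1344,
                       n1 = 1.335, n2 = 1.365, lambda_um = 0.55,
                       background_level = 0.15, intensity_scale = 0.165,
                       noise_sigma = 0.01,
                       speckles = list(count_per_cell = 0, amplitude = 0.12, radius_px = 2),
                       debris = list(count = 0, radius_px = 4, level = 0.25),
                       seed = 1L) {
  cells <- as.data.frame(cells)
  need <- c("center_row", "center_col", "a_px", "b_px", "theta_rad", "height_um")
  if (nrow(cells) > 0 && !all(need %in% names(cells)))
    cellseg_stop("cellseg_param_error", "cells must have columns %s",
                 paste(need, collapse = ", "))
  if (is.null(cells$profile)) cells$profile <- rep("cosine_dome", nrow(cells))
  if (n2 <= n1)
    cellseg_stop("cellseg_param_error",
                 "negative phase contrast requires n2 > n1 (bright cells)")
  if (lambda_um <= 0) cellseg_stop("cellseg_param_error", "lambda_um must be > 0")
  if (nrow(cells) > 0 && (any(cells$a_px <= 0) || any(cells$b_px <= 0) ||
                          any(cells$height_um <= 0)))
    cellseg_stop("cellseg_param_error", "cell geometry must be positive")
  structure(list(cells = cells, height_px = height_px, width_px = width_px,
                 n1 = n1, n2 = n2, lambda_um = lambda_um,
                 background_level = background_level,
                 intensity_scale = intensity_scale,
                 noise_sigma = noise_sigma, speckles = speckles,
                 debris = debris, seed = as.integer(seed),
                 rng_kind = "Mersenne-Twister/Inversion"),
            class = "scene_spec")
}

# Dome profile as a function of normalized elliptical radius in [0, 1].
dome_profile <- function(rn, height_um, profile) {
  switch(profile,
    cosine_dome = height_um * cos(pi * rn / 2)^2,
    gaussian_dome = height_um * (exp(-4 * rn^2) - exp(-4)) / (1 - exp(-4)),
    cellseg_stop("cellseg_param_error", "unknown profile %s", profile))
}

# Per-cell height contribution on the full grid (0 outside the ellipse).
cell_height_field <- function(spec, i) {
  cl <- spec$cells[i, ]
  h <- matrix(0, spec$height_px, spec$width_px)
  rmax <- max(cl$a_px, cl$b_px)
  r0 <- max(1L, floor(cl$center_row - rmax) + 1L)
  r1 <- min(spec$height_px, ceiling(cl$center_row + rmax) + 1L)
  c0 <- max(1L, floor(cl$center_col - rmax) + 1L)
  c1 <- min(spec$width_px, ceiling(cl$center_col + rmax) + 1L)
  if (r1 < r0 || c1 < c0) return(h)
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - 1 - cl$center_row, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - cl$center_col)
  u <-  dx * cos(cl$theta_rad) + dy * sin(cl$theta_rad)
  v <- -dx * sin(cl$theta_rad) + dy * cos(cl$theta_rad)
  rn <- sqrt((u / cl$a_px)^2 + (v / cl$b_px)^2)
  inside <- rn < 1
  block <- matrix(0, length(rows), length(cols))
  block[inside] <- dome_profile(rn[inside], cl$height_um, cl$profile)
  h[rows, cols] <- block
  h
}

#' Height map of a synthetic scene
#'
#' Realizes every cell's dome height profile (apex above the nucleus,
#' falling to zero at the ellipse boundary) on the pixel grid.
#' Overlapping cells combine by pointwise maximum: touching cells sit
#' side by side, they do not stack.
#'
#' @param spec A [scene_spec].
#' @return List with `heights` (matrix, um) and `truth_labels` (integer
#'   matrix: pixelwise argmax of the per-cell height contributions).
#' @export
height_map <- function(spec) {
  H <- matrix(0, spec$height_px, spec$width_px)
  lab <- matrix(0L, spec$height_px, spec$width_px)
  for (i in seq_len(nrow(spec$cells))) {
    hi <- cell_height_field(spec, i)
    takeover <- hi > H
    H[takeover] <- hi[takeover]
    lab[takeover] <- i
  }
  list(heights = H, truth_labels = lab)
}

#' Render a height map into a negative phase contrast image
#'
#' Applies the linear optics model: phase shift
#' `dphi = 2*pi*(n2 - n1)*h/lambda`, raw intensity `I = 1 + 2*dphi`,
#' then display scaling `background + intensity_scale*(I - 1)`, plus
#' seeded organelle speckles, debris blobs and Gaussian noise, clipped to
#' \[0, 1\].
#'
#' @param heights Height matrix in um (see [height_map]), or the list
#'   returned by [height_map].
#' @param spec A [scene_spec].
#' @return An [image2d]. A warning is issued if more than 10% of pixels
#'   clip.
#' @export
render_intensity <- function(heights, spec) {
  if (is.list(heights)) heights <- heights$heights
  if (min(heights) < 0) cellseg_stop("cellseg_param_error", "heights must be >= 0")
  dphi <- phase_shift(heights, spec$n1, spec$n2, spec$lambda_um)
  img <- spec$background_level + spec$intensity_scale * 2 * dphi
  with_scene_rng(spec$seed, {
    img <- img + speckle_field(spec)
    img <- img + debris_field(spec, heights)
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
  })
  clipped <- mean(img < 0 | img > 1)
  if (clipped > 0.1)
    warning(sprintf("%.1f%% of pixels clipped; scene parameters overdrive the display range",
                    100 * clipped))
  image2d(pmin(pmax(img, 0), 1))
}

#' Phase shift of a transparent object
#'
#' `dphi = 2*pi*(n2 - n1)*h/lambda`.
#'
#' @param h_um Thickness (um), scalar or matrix.
#' @param n1,n2 Refractive indices of medium and object.
#' @param lambda_um Wavelength (um).
#' @return Phase shift in radians, same shape as `h_um`.
#' @export
phase_shift <- function(h_um, n1, n2, lambda_um) {
  2 * pi * (n2 - n1) * h_um / lambda_um
}

# Evaluate expr with the scene RNG, restoring the caller's RNG state.
with_scene_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  eval.parent(substitute(expr))
}

# Bright organelle-like bumps inside cells (pseudo-peak sources), placed
# uniformly in the annulus 0.25 <= rn <= 0.7 of each cell.
speckle_field <- function(spec) {
  out <- matrix(0, spec$height_px, spec$width_px)
  sp <- spec$speckles
  if (sp$count_per_cell <= 0 || nrow(spec$cells) == 0) return(out)
  for (i in seq_len(nrow(spec$cells))) {
    cl <- spec$cells[i, ]
    for (s in seq_len(sp$count_per_cell)) {
      rn <- runif(1, 0.25, 0.7)
      ang <- runif(1, 0, 2 * pi)
      u <- rn * cl$a_px * cos(ang); v <- rn * cl$b_px * sin(ang)
      cy <- cl$center_row + u * sin(cl$theta_rad) + v * cos(cl$theta_rad)
      cx <- cl$center_col + u * cos(cl$theta_rad) - v * sin(cl$theta_rad)
      out <- add_gaussian_bump(out, cy, cx, sp$radius_px, sp$amplitude)
    }
  }
  out
}

# Cell-free bright blobs mimicking debris; rejection-sampled onto
# height-free background.
debris_field <- function(spec, heights) {
  out <- matrix(0, spec$height_px, spec$width_px)
  db <- spec$debris
  if (db$count <= 0) return(out)
  for (i in seq_len(db$count)) {
    for (att in seq_len(1000)) {
      cy <- runif(1, 8, spec$height_px - 9)
      cx <- runif(1, 8, spec$width_px - 9)
      if (heights[round(cy) + 1, round(cx) + 1] == 0) break
    }
    r <- if (length(db$radius_px) > 1) runif(1, db$radius_px[1], db$radius_px[2])
         else db$radius_px
    out <- add_gaussian_bump(out, cy, cx, r, db$level)
  }
  out
}

add_gaussian_bump <- function(mat, cy, cx, radius, amplitude) {
  h <- nrow(mat); w <- ncol(mat)
  ext <- ceiling(3 * radius)
  r0 <- max(1, floor(cy) - ext + 1); r1 <- min(h, ceiling(cy) + ext + 1)
  c0 <- max(1, floor(cx) - ext + 1); c1 <- min(w, ceiling(cx) + ext + 1)
  if (r1 < r0 || c1 < c0) return(mat)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - 1 - cy)^2, rep(1, length(cols))) +
        outer(rep(1, length(rows)), (cols - 1 - cx)^2)
  mat[rows, cols] <- mat[rows, cols] + amplitude * exp(-d2 / (2 * radius^2))
  mat
}

#' Generate a synthetic scene with ground truth
#'
#' Deterministic given `spec$seed`: realizes the height map, renders the
#' intensity image, and returns the ground truth (label map from the dome
#' supports, true apex positions, per-cell areas).
#'
#' @param spec A [scene_spec].
#' @return List with `image` ([image2d]), `truth` (list: `label_map`,
#'   `peaks` data frame with 0-based `row`/`col`, `area_px` vector), and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  hm <- height_map(spec)
  img <- render_intensity(hm$heights, spec)
  n <- nrow(spec$cells)
  areas <- if (n) tabulate(hm$truth_labels[hm$truth_labels > 0L], nbins = n) else integer(0)
  truth <- list(
    label_map = label_map(hm$truth_labels),
    peaks = if (n) data.frame(row = spec$cells$center_row,
                              col = spec$cells$center_col)
            else data.frame(row = numeric(0), col = numeric(0)),
    area_px = areas)
  list(image = img, truth = truth, spec = spec)
}
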