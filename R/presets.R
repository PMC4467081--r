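#' Scene presets
#'
#' Ready-made [scene_spec]s covering the scenarios the segmenter must
#' handle: an isolated cell, a speckled cell (pseudo-peak sources), a
#' k-cell clump, and a full field of view at the density and coverage of
#' a typical low-magnification culture image (around 130 cells per
#' 1344 x 1024 frame, 12-20% coverage, roughly 15% of cells in clumps).
#'
#' Cell geometry is sampled once per seed: semi-axes 18-30 px (equivalent
#' radii around 15 um at 0.67 um/px), apex heights 2-6 um.
#'
#' @param seed Integer seed.
#' @param noise_sigma Additive noise sd. Defaults: 0.01 (0 for
#'   `scene_single`, which is the clean reference phantom).
#' @name scene_presets
NULL

sample_cell_geometry <- function(n) {
  a <- runif(n, 18, 30)
  data.frame(a_px = a, b_px = a * runif(n, 0.72, 1),
             theta_rad = runif(n, 0, pi), height_um = runif(n, 2, 6))
}

#' @rdname scene_presets
#' @param size Frame side (px) for the single-cell presets. Default 128.
#' @export
#' @details `scene_standard()` is the canonical reference phantom for
#'   the contour-dynamics studies (convergence, gain ordering, threshold
#'   robustness): a fixed circular cell of semi-axes 22 px and apex
#'   height 5 um, contrasty enough that even the stiff alpha = beta = 1
#'   snake has an equilibrium part-way down the dome. Only the noise
#'   realization depends on the seed.
scene_standard <- function(seed = 1, size = 128, noise_sigma = 0.01) {
  cells <- data.frame(center_row = (size - 1) / 2, center_col = (size - 1) / 2,
                      a_px = 22, b_px = 22, theta_rad = 0, height_um = 5,
                      profile = "cosine_dome")
  scene_spec(cells, height_px = size, width_px = size,
             noise_sigma = noise_sigma, seed = seed)
}

#' @rdname scene_presets
#' @export
scene_single <- function(seed = 1, size = 128, noise_sigma = 0) {
  geo <- with_scene_rng(seed + 1000L, sample_cell_geometry(1))
  cells <- cbind(center_row = (size - 1) / 2, center_col = (size - 1) / 2,
                 geo, profile = "cosine_dome")
  scene_spec(cells, height_px = size, width_px = size,
             noise_sigma = noise_sigma, seed = seed)
}

#' @rdname scene_presets
#' @param count_per_cell,amplitude,radius_px Speckle parameters (bright
#'   organelle-like bumps). Defaults: 3 speckles of amplitude 0.18,
#'   radius 1.5 px — sharp enough that their local gradient beats the
#'   dome slope and raw images show pseudo-peaks.
#' @export
scene_speckled <- function(seed = 1, size = 128, noise_sigma = 0.01,
                           count_per_cell = 3, amplitude = 0.18,
                           radius_px = 1.5) {
  sp <- scene_single(seed, size, noise_sigma)
  sp$speckles <- list(count_per_cell = count_per_cell,
                      amplitude = amplitude, radius_px = radius_px)
  sp
}

#' @rdname scene_presets
#' @param k Number of touching cells in the clump (2-6).
#' @export
scene_clump <- function(k = 4, seed = 1, size = 192, noise_sigma = 0.01) {
  stopifnot(k >= 2, k <= 6)
  cells <- with_scene_rng(seed + 2000L, {
    geo <- sample_cell_geometry(k)
    ctr <- (size - 1) / 2
    pos <- matrix(NA_real_, k, 2)
    pos[1, ] <- c(ctr, ctr)
    for (i in 2:k) {
      ok <- FALSE
      for (att in 1:2000) {
        j <- sample.int(i - 1, 1)  # attach to an already placed cell
        ang <- runif(1, 0, 2 * pi)
        # touching: centers closer than the sum of mean radii
        dist <- 0.75 * (mean(as.numeric(geo[i, c("a_px", "b_px")])) +
                        mean(as.numeric(geo[j, c("a_px", "b_px")])))
        cand <- pos[j, ] + dist * c(sin(ang), cos(ang))
        dmin <- min(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                                  matrix(cand, i - 1, 2, byrow = TRUE))^2)))
        rmax <- max(geo$a_px[i], geo$b_px[i])
        if (dmin >= 16 && all(cand > rmax + 2) && all(cand < size - rmax - 3)) {
          pos[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) cellseg_stop("cellseg_generation_error",
                            "could not place clump cell %d", i)
    }
    cbind(center_row = pos[, 1], center_col = pos[, 2], geo,
          profile = "cosine_dome")
  })
  scene_spec(cells, height_px = size, width_px = size,
             noise_sigma = noise_sigma, seed = seed)
}

#' @rdname scene_presets
#' @param n_cells Number of cells in the field preset. Default 130.
#' @param height_px,width_px Frame size. Defaults 1024 x 1344.
#' @param clustered_frac Fraction of cells placed in touching clumps
#'   (pairs/triples). Default 0.15.
#' @param debris_count Cell-free bright blobs added to the field.
#'   Default 3.
#' @param speckle_count Speckles per cell. Default 2.
#' @export
scene_field <- function(n_cells = 130, seed = 1,
                        height_px = 1024, width_px = 1344,
                        clustered_frac = 0.15, noise_sigma = 0.01,
                        debris_count = 3, speckle_count = 2) {
  cells <- with_scene_rng(seed + 3000L, {
    geo <- sample_cell_geometry(n_cells)
    pos <- matrix(NA_real_, n_cells, 2)
    rad <- (geo$a_px + geo$b_px) / 2
    n_clustered <- round(clustered_frac * n_cells)
    # clump membership: greedy pairs/triples among the first n_clustered
    clump_of <- integer(n_cells)
    cid <- 0L; i <- 1L
    while (i <= n_clustered) {
      cid <- cid + 1L
      sz <- min(sample(2:3, 1), n_clustered - i + 1L)
      if (sz < 2) sz <- 2L
      clump_of[i:min(n_cells, i + sz - 1L)] <- cid
      i <- i + sz
    }
    place <- function(i) {
      rmax <- max(geo$a_px[i], geo$b_px[i])
      anchor_set <- if (clump_of[i] > 0L)
        which(clump_of == clump_of[i] & seq_len(n_cells) < i & !is.na(pos[, 1]))
      else integer(0)
      for (att in seq_len(10000)) {
        if (length(anchor_set)) {
          j <- anchor_set[sample.int(length(anchor_set), 1)]
          ang <- runif(1, 0, 2 * pi)
          cand <- pos[j, ] + 0.75 * (rad[i] + rad[j]) * c(sin(ang), cos(ang))
        } else {
          cand <- c(runif(1, rmax + 2, height_px - rmax - 3),
                    runif(1, rmax + 2, width_px - rmax - 3))
        }
        if (any(cand < rmax + 2) || cand[1] > height_px - rmax - 3 ||
            cand[2] > width_px - rmax - 3) next
        prev <- which(!is.na(pos[, 1]))
        if (length(prev)) {
          dd <- sqrt(rowSums((pos[prev, , drop = FALSE] -
                              matrix(cand, length(prev), 2, byrow = TRUE))^2))
          lim <- ifelse(clump_of[prev] > 0L & clump_of[prev] == clump_of[i],
                        16, rad[prev] + rad[i] + 4)
          if (any(dd < lim)) next
        }
        return(cand)
      }
      cellseg_stop("cellseg_generation_error",
                   "could not place cell %d after 10000 attempts", i)
    }
    for (i in seq_len(n_cells)) pos[i, ] <- place(i)
    cbind(center_row = pos[, 1], center_col = pos[, 2], geo,
          profile = "cosine_dome")
  })
  scene_spec(cells, height_px = height_px, width_px = width_px,
             noise_sigma = noise_sigma,
             speckles = list(count_per_cell = speckle_count,
                             amplitude = 0.1, radius_px = 2),
             debris = list(count = debris_count, radius_px = c(2.5, 5.5),
                           level = 0.25),
             seed = seed)
}

#' Radially symmetric test phantom
#'
#' A single circular "cell": intensity plateau `i_cell` inside
#' `r_plateau`, cosine falloff to background `i_bg` between `r_plateau`
#' and `r_outer`. Its radial symmetry makes the snake equilibrium
#' accessible to a one-dimensional circle-restricted energy search,
#' which is the package's reference oracle for the contour expansion
#' dynamics.
#'
#' @param size Frame side, default 72 px.
#' @param r_plateau,r_outer Plateau and support radii (px).
#' @param i_cell,i_bg Plateau and background intensities.
#' @return An [image2d] with attributes `center` (0-based (x, y)) and
#'   `r_outer`.
#' @export
radial_phantom <- function(size = 72, r_plateau = 15, r_outer = 25,
                           i_cell = 0.8, i_bg = 0.2) {
  ctr <- (size - 1) / 2
  d <- sqrt(outer((seq_len(size) - 1 - ctr)^2,
                  (seq_len(size) - 1 - ctr)^2, "+"))
  img <- matrix(i_bg, size, size)
  ramp <- d >= r_plateau & d < r_outer
  img[d < r_plateau] <- i_cell
  img[ramp] <- i_bg + (i_cell - i_bg) *
    cos(pi / 2 * (d[ramp] - r_plateau) / (r_outer - r_plateau))^2
  out <- image2d(img)
  attr(out, "center") <- c(x = ctr, y = ctr)
  attr(out, "r_outer") <- r_outer
  out
}
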