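#' Snake (active contour) parameters
#'
#' Parameters of the edge-based parametric active contour used by the
#' contour expansion method. The contour v(s) minimizes an energy with
#' internal tension (`alpha`) and rigidity (`beta`) terms plus an external
#' image energy proportional to the local light intensity; its
#' Euler-Lagrange equation is stepped semi-implicitly with viscosity
#' `gamma` (the internal terms are treated implicitly, the image force
#' explicitly). Iteration stops when the mean intensity-gradient magnitude
#' along the contour changes by less than `eps_converge` for `patience`
#' consecutive steps.
#'
#' @param alpha Tension gain (first-derivative penalty). Default 0.01.
#' @param beta Rigidity gain (second-derivative penalty). Default 0.01.
#' @param gamma Viscosity / inverse time step of the semi-implicit
#'   update; smaller values take larger steps. Default 0.05.
#' @param kappa Weight of the external image force `F = -kappa * grad(I)`,
#'   which pushes vertices down the intensity slope and hence outward on a
#'   bright convex cell. Default 2.
#' @param eps_converge Convergence tolerance on the change of the mean
#'   gradient magnitude along the contour: 0.002 on the 8-bit intensity
#'   scale, i.e. `0.002/255` in normalized units. On the normalized
#'   scale 0.002 would exceed the per-step metric change of a moving
#'   contour on faint cells and stop it mid-slope.
#' @param patience Consecutive sub-tolerance steps required to stop.
#'   Default 10.
#' @param max_iter Iteration cap; reaching it flags the contour as
#'   non-converged. Default 500.
#' @param resample_spacing_px Uniform vertex spacing re-imposed after each
#'   iteration. Default 2.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.01, beta = 0.01, gamma = 0.05, kappa = 2,
                         eps_converge = 0.002 / 255, patience = 10,
                         max_iter = 500,
                         resample_spacing_px = 2) {
  if (alpha < 0 || beta < 0) cellseg_stop("cellseg_param_error", "alpha, beta must be >= 0")
  if (gamma <= 0) cellseg_stop("cellseg_param_error", "gamma must be > 0")
  if (eps_converge <= 0) cellseg_stop("cellseg_param_error", "eps_converge must be > 0")
  if (patience < 1) cellseg_stop("cellseg_param_error", "patience must be >= 1")
  if (max_iter < patience) cellseg_stop("cellseg_param_error", "max_iter must be >= patience")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 eps_converge = eps_converge, patience = patience,
                 max_iter = max_iter, resample_spacing_px = resample_spacing_px),
            class = "snake_params")
}

#' Internal-energy system matrix of the snake
#'
#' Assembles the cyclic pentadiagonal operator discretizing the internal
#' energy gradient of a closed contour with n vertices at uniform spacing
#' d: `alpha` times the (negated) periodic second difference plus `beta`
#' times the periodic fourth difference, normalized by d^2 and d^4, plus
#' `gamma` on the diagonal. The matrix is circulant and every row sums to
#' `gamma` (the derivative stencils sum to zero), so a constant contour
#' is a fixed point of the implicit step in the absence of image force.
#'
#' @param n Number of vertices (>= 8).
#' @param params A [snake_params].
#' @return An n x n matrix `gamma*I + alpha*K2 + beta*K4`.
#' @export
build_internal_system <- function(n, params) {
  if (n < 8) cellseg_stop("cellseg_param_error", "need n >= 8 vertices")
  d <- params$resample_spacing_px
  # stiffness stencils (positive semidefinite): -D2 and +D4
  k2 <- c(2, -1, rep(0, n - 3), -1) / d^2
  k4 <- c(6, -4, 1, rep(0, n - 5), 1, -4) / d^4
  row1 <- params$gamma * c(1, rep(0, n - 1)) + params$alpha * k2 + params$beta * k4
  # circulant assembly: row k+1 is row k rotated right by one
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, ] <- row1[((seq_len(n) - i) %% n) + 1]
  A
}

#' External image force at contour vertices
#'
#' Samples the intensity gradient field bilinearly at each subpixel
#' vertex and returns `F = -kappa * (gx, gy)`: the force points down the
#' intensity slope, i.e. outward on a bright convex cell body, driving
#' the contour expansion. Vertices outside the image are clamped to the
#' nearest border pixel.
#'
#' @param field A [gradient_field].
#' @param points A `cell_contour` or N x 2 matrix of (x, y) vertices.
#' @param kappa Force weight (> 0).
#' @return N x 2 matrix of force vectors (fx, fy).
#' @export
external_force <- function(field, points, kappa = 2) {
  p <- as.matrix(unclass(points))
  fx <- -kappa * bilinear_interp(field$gx, p[, 1], p[, 2])
  fy <- -kappa * bilinear_interp(field$gy, p[, 1], p[, 2])
  cbind(fx = fx, fy = fy)
}

#' Evolve a snake by contour expansion
#'
#' Iterates the semi-implicit update
#' `v[t+1] = solve(gamma*I + alpha*K2 + beta*K4, gamma*v[t] + F(v[t]))`
#' per coordinate, resampling the contour to uniform arc-length spacing
#' after every step and clamping vertices to the image bounds. The
#' convergence trace records the mean interpolated gradient magnitude
#' along the contour at each iteration; evolution stops once its
#' step-to-step change stays below `eps_converge` for `patience`
#' consecutive iterations, or at `max_iter`.
#'
#' @param initial A [cell_contour] seeding the snake (typically the
#'   thresholded mask boundary, inside the true cell boundary).
#' @param image An [image2d] (used for bounds).
#' @param field A [gradient_field] of the (smoothed) intensity.
#' @param params A [snake_params].
#' @param min_area_px Abort threshold: the contour collapsing below this
#'   enclosed area (or below 8 vertices) raises a degenerate-contour
#'   error. Default 4.
#' @param cell_id Integer used in error messages and logs.
#' @return List with `contour` (converged [cell_contour]), `trace`
#'   (numeric vector of mean |grad I| per iteration), `iterations`, and
#'   `converged` (logical; `FALSE` when `max_iter` was hit).
#' @export
evolve_contour <- function(initial, image, field, params = snake_params(),
                           min_area_px = 4, cell_id = NA_integer_) {
  h <- nrow(field$mag); w <- ncol(field$mag)
  v <- as.matrix(unclass(initial))
  d <- params$resample_spacing_px
  sys_cache <- new.env(parent = emptyenv())
  trace <- numeric(0)
  m_prev <- NA_real_
  calm <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    n <- nrow(v)
    key <- as.character(n)
    Ainv <- get0(key, envir = sys_cache)
    if (is.null(Ainv)) {
      Ainv <- solve(build_internal_system(n, params))
      assign(key, Ainv, envir = sys_cache)
    }
    f <- external_force(field, v, params$kappa)
    v <- Ainv %*% (params$gamma * v + f)
    v[, 1] <- pmin(pmax(v[, 1], 0), w - 1)
    v[, 2] <- pmin(pmax(v[, 2], 0), h - 1)
    v <- tryCatch(resample_closed(v, d), error = function(e) e)
    if (inherits(v, "error") || nrow(v) < 8 || abs(signed_area(v)) < min_area_px)
      cellseg_stop("cellseg_degenerate_contour",
                   "contour collapsed during evolution (cell %s, iteration %d)",
                   cell_id, iter)
    m <- mean(bilinear_interp(field$mag, v[, 1], v[, 2]))
    trace <- c(trace, m)
    if (!is.na(m_prev) && abs(m - m_prev) < params$eps_converge) {
      calm <- calm + 1L
      if (calm >= params$patience) { converged <- TRUE; break }
    } else calm <- 0L
    m_prev <- m
  }
  list(contour = cell_contour(v), trace = trace,
       iterations = iter, converged = converged)
}
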