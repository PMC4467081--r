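test_that("the internal system matrix matches explicit stencil assembly", {
  # independent assembly: loop over vertices, add gamma, tension and
  # rigidity stencils with modular indexing
  assemble <- function(n, alpha, beta, gamma, d) {
    A <- matrix(0, n, n)
    w2 <- c(-1, 2, -1) / d^2
    w4 <- c(1, -4, 6, -4, 1) / d^4
    for (i in seq_len(n)) {
      A[i, i] <- A[i, i] + gamma
      for (o in -1:1) A[i, ((i - 1 + o) %% n) + 1] <-
          A[i, ((i - 1 + o) %% n) + 1] + alpha * w2[o + 2]
      for (o in -2:2) A[i, ((i - 1 + o) %% n) + 1] <-
          A[i, ((i - 1 + o) %% n) + 1] + beta * w4[o + 3]
    }
    A
  }
  for (ps in list(snake_params(alpha = 1, beta = 0, gamma = 1),
                  snake_params(alpha = 0.3, beta = 0.7, gamma = 0.05),
                  snake_params(alpha = 0.01, beta = 0.01))) {
    for (n in c(8, 13)) {
      A <- build_internal_system(n, ps)
      expect_equal(A, assemble(n, ps$alpha, ps$beta, ps$gamma,
                               ps$resample_spacing_px), tolerance = 1e-12)
      expect_equal(rowSums(A), rep(ps$gamma, n), tolerance = 1e-12)
      # circulant: each row is the previous row rotated by one
      for (i in 2:n) expect_equal(A[i, ], A[i - 1, c(n, 1:(n - 1))])
    }
  }
  # no internal energy: system reduces to gamma * identity
  A0 <- build_internal_system(10, snake_params(alpha = 0, beta = 0, gamma = 2))
  expect_equal(A0, diag(2, 10), tolerance = 1e-12)
})

test_that("the external force is the down-slope interpolated gradient", {
  gx <- matrix(0, 8, 8); gy <- matrix(0, 8, 8)
  gx[3, 4] <- 0.2; gx[3, 5] <- 0.4
  f <- structure(list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2)),
                 class = "gradient_field")
  # at a lattice point the interpolation is exact
  F1 <- external_force(f, rbind(c(3, 2)), kappa = 1)
  expect_equal(unname(F1[1, 1]), -0.2, tolerance = 1e-12)
  # midpoint between gx = 0.2 and 0.4
  F2 <- external_force(f, rbind(c(3.5, 2)), kappa = 1)
  expect_equal(unname(F2[1, 1]), -0.3, tolerance = 1e-12)
  expect_equal(unname(F2[1, 2]), 0, tolerance = 1e-12)

  # inside a radial bright bump every force has positive outward component
  n <- 41; ctr <- 20
  d2 <- outer((seq_len(n) - 1 - ctr)^2, (seq_len(n) - 1 - ctr)^2, "+")
  fb <- gradient_field(0.6 * exp(-d2 / (2 * 8^2)) + 0.2)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- cbind(ctr + 6 * cos(th), ctr + 6 * sin(th))
  Fr <- external_force(fb, pts, kappa = 2)
  outward <- (pts[, 1] - ctr) * Fr[, 1] + (pts[, 2] - ctr) * Fr[, 2]
  expect_true(all(outward > 0))
})

test_that("a contour is a fixed point when all forces vanish", {
  flat <- image2d(matrix(0.5, 64, 64))
  f <- gradient_field(flat)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cell_contour(cbind(31.5 + 12 * cos(th), 31.5 + 12 * sin(th)))
  res <- evolve_contour(circ, flat, f,
                        snake_params(alpha = 0, beta = 0))
  expect_true(res$converged)
  # uniform resampling nudges vertices onto polygon chords; the contour
  # stays put up to that discretization slack
  expect_equal(mean_radius(res$contour, c(31.5, 31.5)), 12, tolerance = 0.005)
})

test_that("the snake equilibrium matches circle-restricted energy minimization", {
  ph <- radial_phantom(size = 96)
  ctr <- attr(ph, "center")
  field <- gradient_field(ph)
  init <- extract_initial_contour(
    label_components(binarize(ph, 0.5), min_area_px = 20)$labels == 1)
  params <- snake_params()
  res <- evolve_contour(init, ph, field, params)
  expect_true(res$converged)
  r_snake <- mean_radius(res$contour, ctr)
  grid <- seq(10, 35, by = 0.25)
  n_fix <- round(2 * pi * 22.5 / params$resample_spacing_px)
  E <- vapply(grid, function(r) circle_energy(ph$data, ctr, r, n_fix, params),
              numeric(1))
  expect_lt(abs(r_snake - grid[which.min(E)]), 1.5)
})

test_that("expansion never ends below the thresholded seed area", {
  for (s in c(2, 6)) {
    g <- generate_scene(scene_single(seed = s))
    sm <- smooth_image(g$image, 3)
    field <- gradient_field(smooth_image(g$image, 1))
    lm <- label_components(binarize(sm, 45 / 255), min_area_px = 50)
    init <- extract_initial_contour(lm$labels == 1)
    res <- evolve_contour(init, g$image, field, snake_params())
    expect_gte(compute_area(res$contour)$area_px,
               0.98 * compute_area(init)$area_px)
  }
})

test_that("a collapsing contour raises a degenerate-contour error", {
  flat <- image2d(matrix(0.5, 64, 64))
  f <- gradient_field(flat)
  th <- seq(0, 2 * pi, length.out = 31)[-31]
  circ <- cell_contour(cbind(31.5 + 10 * cos(th), 31.5 + 10 * sin(th)))
  # huge tension, tolerance too tight to trigger the stopping rule
  expect_error(
    evolve_contour(circ, flat, f,
                   snake_params(alpha = 200, beta = 0, eps_converge = 1e-15,
                                patience = 10, max_iter = 100),
                   min_area_px = 40, cell_id = 7L),
    "cell 7", class = "cellseg_degenerate_contour")
})
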