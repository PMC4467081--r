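test_that("mean and absolute threshold methods follow their definitions", {
  img <- image2d(matrix(0.3, 16, 16))
  expect_equal(compute_threshold(img, threshold_spec("mean_offset", offset = 0.1)),
               0.4, tolerance = 1e-12)
  expect_equal(compute_threshold(img, threshold_spec("absolute",
                                                     absolute_value = 45 / 255)),
               45 / 255, tolerance = 1e-12)
  expect_warning(compute_threshold(img, threshold_spec("mean_offset", offset = 0.9)),
                 "outside")
  expect_error(threshold_spec("absolute"), class = "cellseg_param_error")
})

test_that("otsu threshold maximizes between-class variance on 256 bins", {
  x <- matrix(c(rep(0.2, 100), rep(0.8, 156)), 16, 16)
  thr <- compute_threshold(x, threshold_spec("otsu_offset"))
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  # brute-force oracle: between-class variance at the returned threshold
  # must equal the maximum over all 256-bin cut points
  bcv <- function(mat, t) {
    lo <- mat[mat <= t]; hi <- mat[mat > t]
    if (!length(lo) || !length(hi)) return(0)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2 / length(mat)^2
  }
  cuts <- seq(0, 1, length.out = 257)[-257]
  expect_equal(bcv(x, thr), max(vapply(cuts, function(t) bcv(x, t), numeric(1))),
               tolerance = 1e-9)
})

test_that("binarization uses a strict inequality and respects bounds", {
  m <- matrix(c(0.4, 0.6), 1, 2)
  expect_identical(binarize(m, 0.4), matrix(c(FALSE, TRUE), 1, 2))
  pos <- matrix(runif(64, 0.01, 1), 8, 8)
  expect_true(all(binarize(pos, 0)))
  expect_false(any(binarize(pos, 1)))
  expect_error(binarize(pos, 1.2), class = "cellseg_param_error")
})

test_that("components are 8-connected and filtered by area", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch
  expect_identical(label_components(m, min_area_px = 0)$n_components, 1L)

  big <- matrix(FALSE, 60, 120)
  big[2:11, 2:2] <- TRUE                   # area 10
  big[20:39, 10:24] <- TRUE                # area 300
  big[5:29, 60:79] <- TRUE                 # area 500
  lm <- label_components(big, min_area_px = 50)
  expect_identical(lm$n_components, 2L)
  areas <- tabulate(lm$labels[lm$labels > 0])
  expect_identical(areas, c(500L, 300L))   # descending-area label order

  expect_identical(label_components(matrix(FALSE, 8, 8))$n_components, 0L)
})

test_that("8-connected labeling matches an exhaustive flood-fill oracle", {
  flood_count <- function(b) {
    seen <- matrix(FALSE, nrow(b), ncol(b)); n <- 0
    for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b))) {
      if (!b[i, j] || seen[i, j]) next
      n <- n + 1
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; cc <- p[2] + dc
          if (r >= 1 && r <= nrow(b) && cc >= 1 && cc <= ncol(b) &&
              b[r, cc] && !seen[r, cc]) {
            seen[r, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(r, cc)
          }
        }
      }
    }
    n
  }
  set.seed(21)
  for (rep in 1:5) {
    b <- matrix(runif(20 * 20) < 0.35, 20, 20)
    expect_identical(label_components(b, min_area_px = 0,
                                      fill_holes = FALSE)$n_components,
                     as.integer(flood_count(b)))
  }
})

test_that("foreground shrinks monotonically with the threshold", {
  g <- generate_scene(scene_single(seed = 9))
  sm <- smooth_image(g$image, 3)
  prev <- NULL
  for (t8 in c(35, 45, 55, 65)) {
    fg <- binarize(sm, t8 / 255)
    if (!is.null(prev)) expect_true(all(prev[fg]))  # fg(t2) subset of fg(t1)
    prev <- fg
  }
  lm <- label_components(binarize(sm, 45 / 255), min_area_px = 50,
                         fill_holes = FALSE)
  expect_true(all(sm$data[lm$labels > 0] > 45 / 255))
})
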