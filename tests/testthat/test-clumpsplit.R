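test_that("regional maxima match the exhaustive plateau oracle", {
  # two isolated 1-px maxima amid a constant level
  m <- matrix(0.5, 5, 7); m[2, 2] <- 0.9; m[4, 6] <- 0.9
  got <- regional_maxima(m)
  expect_identical(nrow(got), 2L)
  expect_equal(got$row, c(1, 3)); expect_equal(got$col, c(1, 5))

  # a flat plateau reports one peak at its centroid
  p <- matrix(0.2, 9, 9); p[4:6, 4:6] <- 0.8
  got <- regional_maxima(p)
  expect_identical(nrow(got), 1L)
  expect_equal(got$row, 4); expect_equal(got$col, 4)

  # a shoulder plateau leading up to a higher value is not a maximum
  sh <- matrix(c(1, 2, 2, 2, 3), 1, 5)[rep(1, 5), ] / 3
  got <- regional_maxima(sh)
  expect_true(all(got$col == 4))

  # randomized agreement with the brute-force oracle
  set.seed(33)
  for (rep in 1:6) {
    x <- matrix(sample(seq(0, 1, by = 0.1), 81, replace = TRUE), 9, 9)
    a <- regional_maxima(x); b <- brute_regional_maxima(x)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$row, b$row, tolerance = 1e-9)
    expect_equal(a$col, b$col, tolerance = 1e-9)
  }
})

test_that("peak detection finds one peak per isolated cell at its apex", {
  g <- generate_scene(scene_single(seed = 12))
  sm <- smooth_image(g$image, 3)
  lm <- label_components(binarize(sm, 45 / 255), min_area_px = 50)
  pk <- detect_peaks(sm, lm, 45 / 255)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$row - g$truth$peaks$row), 1.5)
  expect_lt(abs(pk$col - g$truth$peaks$col), 1.5)
  expect_identical(unname(classify_masks(lm, pk)), 1L)
})

test_that("masks without a surviving peak are coerced to single cells", {
  lm <- label_components(disk_mask(20, 20, 9.5, 9.5, 5), min_area_px = 0)
  empty <- structure(data.frame(row = numeric(0), col = numeric(0),
                                value = numeric(0), label = integer(0)),
                     class = c("peak_set", "data.frame"))
  expect_warning(counts <- classify_masks(lm, empty), "without a detected peak")
  expect_identical(unname(counts), 1L)
})

test_that("nearest-peak partition follows brute-force distances and tie rule", {
  mask <- matrix(FALSE, 5, 11)
  mask[3, 2:10] <- TRUE  # 1 x 9 strip at 0-based cols 1..9
  peaks <- data.frame(row = c(2, 2), col = c(2, 8))  # 0-based strip cols 1, 7
  part <- partition_mask(mask, peaks)
  a <- part$assignment[3, 2:10]
  # cols 1..5 nearer peak 1 (col 5 ties at distance 3 -> lowest index wins)
  expect_identical(a, c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  # conservation and disjointness
  expect_identical(sum(part$assignment > 0), sum(mask))
  expect_identical(partition_mask(mask, peaks)$assignment, part$assignment)

  one <- partition_mask(mask, peaks[1, , drop = FALSE])
  expect_identical(one$assignment > 0, mask)
})

test_that("a four-cell clump partitions into subareas holding their own peaks", {
  g <- generate_scene(scene_clump(4, seed = 2))
  sm <- smooth_image(g$image, 3)
  lm <- label_components(binarize(sm, 45 / 255), min_area_px = 50)
  pk <- detect_peaks(sm, lm, 45 / 255)
  expect_identical(nrow(pk), 4L)
  part <- partition_mask(lm$labels == 1, pk)
  expect_length(part$subcontours, 4)
  for (i in 1:4)
    expect_identical(part$assignment[round(pk$row[i]) + 1,
                                     round(pk$col[i]) + 1], i)
  expect_identical(sum(part$assignment > 0), sum(lm$labels == 1))
})

test_that("contour expansion corrects a deliberately mis-divided pair", {
  g <- generate_scene(scene_clump(2, seed = 8))
  sm <- smooth_image(g$image, 3)
  field <- gradient_field(smooth_image(g$image, 1))
  lm <- label_components(binarize(sm, 45 / 255), min_area_px = 50)
  pk <- detect_peaks(sm, lm, 45 / 255)
  expect_identical(nrow(pk), 2L)
  # shift both peaks 3 px along the inter-peak axis: the division line
  # moves ~3 px off the true valley
  dir <- c(pk$row[2] - pk$row[1], pk$col[2] - pk$col[1])
  dir <- dir / sqrt(sum(dir^2))
  bad <- pk
  bad$row <- pk$row + 3 * dir[1]; bad$col <- pk$col + 3 * dir[2]
  part <- partition_mask(lm$labels == 1, bad)
  res <- refine_clump(part$subcontours, g$image, field, snake_params())
  # rasterize with nearest-(true)-peak overlap resolution and score
  H <- g$image$height_px; W <- g$image$width_px
  labs <- matrix(0L, H, W)
  for (i in 1:2) {
    m <- rasterize_contour(res[[i]]$contour, H, W)
    take <- m & labs == 0L
    labs[take] <- i
    both <- which(m & labs != i & labs > 0L, arr.ind = TRUE)
    if (nrow(both)) {
      di <- (both[, 1] - 1 - pk$row[i])^2 + (both[, 2] - 1 - pk$col[i])^2
      dj <- (both[, 1] - 1 - pk$row[labs[both]])^2 +
            (both[, 2] - 1 - pk$col[labs[both]])^2
      labs[both[di < dj, , drop = FALSE]] <- i
    }
  }
  pred <- label_map(labs)
  ious <- best_iou_per_truth(pred, g$truth$label_map)
  expect_true(all(ious >= 0.8))
})
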