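# Build a label map of nx x ny rectangular "cells" on a padded grid.
block_labels <- function(nx, ny, cell = 3, gap = 2) {
  h <- ny * (cell + gap) + gap; w <- nx * (cell + gap) + gap
  m <- matrix(0L, h, w)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    r0 <- gap + (iy - 1) * (cell + gap) + 1
    c0 <- gap + (ix - 1) * (cell + gap) + 1
    m[r0:(r0 + cell - 1), c0:(c0 + cell - 1)] <- k
  }
  label_map(m)
}

relabel_contiguous <- function(m) {
  u <- sort(unique(m[m > 0L]))
  map <- integer(max(u) + 1L); map[u + 1L] <- seq_along(u)
  label_map(matrix(c(0L, map[-1])[m + 1L], nrow(m), ncol(m)))
}

test_that("a perfect prediction scores zero on every error class", {
  truth <- block_labels(5, 4)
  rep <- match_and_count(truth, truth)
  expect_identical(rep$n_matched, truth$n_components)
  expect_identical(rep$n_overseg_events, 0L)
  expect_identical(rep$n_underseg_events, 0L)
  expect_identical(rep$n_overdetect, 0L)
  expect_equal(rep$rates$overall, 0)
})

test_that("a clump of four cells predicted as eight gives four oversegmentation events", {
  truth <- block_labels(2, 2, cell = 6, gap = 3)
  pred <- truth$labels
  # split every truth cell vertically into two predictions
  for (k in 1:4) {
    px <- which(truth$labels == k, arr.ind = TRUE)
    right <- px[px[, 2] > mean(px[, 2]), , drop = FALSE]
    pred[right] <- k + 4L
  }
  rep <- match_and_count(relabel_contiguous(pred), truth)
  expect_identical(rep$n_pred, 8L)
  expect_identical(rep$n_overseg_events, 4L)
  expect_identical(rep$n_underseg_events, 0L)
})

test_that("error rates reproduce the benchmark arithmetic on 496 cells", {
  truth <- block_labels(31, 16)  # 496 cells
  pred <- truth$labels
  # 7 oversegmentations: split one cell into two
  for (k in 1:7) {
    px <- which(truth$labels == k, arr.ind = TRUE)
    pred[px[px[, 2] > mean(px[, 2]), , drop = FALSE]] <- 600L + k
  }
  # 2 undersegmentations: merge two neighboring cells into one blob
  for (k in c(10, 20)) {
    a <- which(truth$labels == k, arr.ind = TRUE)
    b <- which(truth$labels == k + 1L, arr.ind = TRUE)
    rows <- range(c(a[, 1], b[, 1])); cols <- range(c(a[, 2], b[, 2]))
    pred[rows[1]:rows[2], cols[1]:cols[2]] <- k
    pred[pred == k + 1L] <- k
  }
  # 7 over-detections: blobs in empty background
  for (k in 1:7) pred[1:2, (5 * k):(5 * k + 1)] <- 700L + k
  rep <- match_and_count(relabel_contiguous(pred), truth)
  expect_identical(rep$n_truth, 496L)
  expect_identical(rep$n_overseg_events, 7L)
  expect_identical(rep$n_underseg_events, 2L)
  expect_identical(rep$n_overdetect, 7L)
  expect_equal(100 * rep$rates$overseg, 1.4, tolerance = 0.05)
  expect_equal(100 * rep$rates$underseg, 0.4, tolerance = 0.05)
  expect_equal(100 * rep$rates$overdetect, 1.4, tolerance = 0.05)
  expect_equal(100 * rep$rates$overall, 3.2, tolerance = 0.1)
})

test_that("reports are invariant to label permutation and symmetric under role swap", {
  set.seed(41)
  truth <- block_labels(4, 3, cell = 5, gap = 2)
  pred <- truth$labels
  px <- which(truth$labels == 2L, arr.ind = TRUE)
  pred[px[px[, 1] > mean(px[, 1]), , drop = FALSE]] <- 99L
  pred_lm <- relabel_contiguous(pred)

  perm <- sample(pred_lm$n_components)
  shuffled <- relabel_contiguous(matrix(
    c(0L, perm)[pred_lm$labels + 1L], nrow(pred), ncol(pred)))
  r1 <- match_and_count(pred_lm, truth)
  r2 <- match_and_count(shuffled, truth)
  expect_identical(r1$n_overseg_events, r2$n_overseg_events)
  expect_identical(r1$n_matched, r2$n_matched)

  swap <- match_and_count(truth, pred_lm)
  expect_identical(r1$n_overseg_events, swap$n_underseg_events)
  expect_identical(r1$n_underseg_events, swap$n_overseg_events)

  bad <- label_map(matrix(0L, 4, 4))
  expect_error(match_and_count(bad, truth), class = "cellseg_param_error")
})
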