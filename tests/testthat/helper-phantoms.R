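# Shared fixtures, all built in code.

# Filled disk mask of radius r centered at 0-based (cy, cx) on an h x w grid.
disk_mask <- function(h, w, cy, cx, r) {
  d2 <- outer((seq_len(h) - 1 - cy)^2, (seq_len(w) - 1 - cx)^2, "+")
  d2 <= r^2
}

iou_masks <- function(a, b) sum(a & b) / sum(a | b)

# Best IoU of each truth label against any predicted label.
best_iou_per_truth <- function(pred_lm, truth_lm) {
  vapply(seq_len(truth_lm$n_components), function(tt) {
    tmask <- truth_lm$labels == tt
    cand <- setdiff(unique(pred_lm$labels[tmask]), 0L)
    if (!length(cand)) return(0)
    max(vapply(cand, function(pp) iou_masks(tmask, pred_lm$labels == pp),
               numeric(1)))
  }, numeric(1))
}

# Brute-force regional-maximum oracle: a pixel set is a regional maximum
# iff it is an 8-connected equal-value plateau whose outside neighbors
# are all strictly lower. Enumerates plateaus exhaustively.
brute_regional_maxima <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  seen <- matrix(FALSE, h, w)
  out <- list()
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (seen[i, j]) next
    v <- mat[i, j]
    # flood the equal-value plateau containing (i, j)
    plateau <- matrix(FALSE, h, w)
    stack <- list(c(i, j)); plateau[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r < 1 || r > h || cc < 1 || cc > w) next
        if (!plateau[r, cc] && mat[r, cc] == v) {
          plateau[r, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
    seen[plateau] <- TRUE
    # check every outside neighbor is strictly lower
    ismax <- TRUE
    px <- which(plateau, arr.ind = TRUE)
    for (q in seq_len(nrow(px))) {
      for (dr in -1:1) for (dc in -1:1) {
        r <- px[q, 1] + dr; cc <- px[q, 2] + dc
        if (r < 1 || r > h || cc < 1 || cc > w) next
        if (!plateau[r, cc] && mat[r, cc] >= v) ismax <- FALSE
      }
    }
    if (ismax) out[[length(out) + 1L]] <-
      c(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1, value = v)
  }
  if (!length(out)) return(data.frame(row = numeric(0), col = numeric(0),
                                      value = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$row, df$col), , drop = FALSE]
}

# Circle-restricted discrete snake energy: same discretization the
# evolver descends (chord differences normalized by spacing d, external
# energy kappa * sum of interpolated intensity), fixed vertex count.
circle_energy <- function(img_mat, center_xy, r, n, params) {
  d <- params$resample_spacing_px
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  vx <- center_xy[1] + r * cos(th)
  vy <- center_xy[2] + r * sin(th)
  ch2 <- diff(c(vx, vx[1]))^2 + diff(c(vy, vy[1]))^2
  d2x <- vx[c(2:n, 1)] - 2 * vx + vx[c(n, 1:(n - 1))]
  d2y <- vy[c(2:n, 1)] - 2 * vy + vy[c(n, 1:(n - 1))]
  sum(params$alpha / (2 * d^2) * ch2 +
      params$beta / (2 * d^4) * (d2x^2 + d2y^2) +
      params$kappa * bilinear_interp(img_mat, vx, vy))
}

mean_radius <- function(contour, center_xy) {
  p <- unclass(contour)
  mean(sqrt((p[, 1] - center_xy[1])^2 + (p[, 2] - center_xy[2])^2))
}
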