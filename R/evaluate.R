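#' Score a segmentation against ground truth
#'
#' Counts the three error classes of the standard cell-segmentation
#' taxonomy by overlap analysis of the two label maps:
#' * oversegmentation - more cells detected than truly present in a
#'   region: a truth cell claimed by k >= 2 predictions counts k - 1
#'   events;
#' * undersegmentation - fewer cells detected than present: a prediction
#'   covering m >= 2 truth cells counts m - 1 events;
#' * over-detection - a prediction overlapping no truth cell (debris or
#'   artifact detected as a cell).
#'
#' A prediction is "claimed by" a truth cell when the majority of its
#' pixels lie in that cell; a prediction "covers" a truth cell when it
#' holds the majority of that cell's pixels. Matches are the remaining
#' one-to-one pairs with IoU at or above `iou_min`. Rates are counts
#' divided by the number of truth cells.
#'
#' @param pred,truth [label_map]s of identical shape.
#' @param iou_min IoU floor for a one-to-one match, in (0, 1).
#'   Default 0.5.
#' @return An object of class `eval_report`: counts (`n_truth`, `n_pred`,
#'   `n_matched`, `n_overseg_events`, `n_underseg_events`,
#'   `n_overdetect`) and `rates` (each count over `n_truth`, with
#'   `overall = (overseg + underseg + overdetect) / n_truth`).
#' @export
match_and_count <- function(pred, truth, iou_min = 0.5) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!all(dim(pred$labels) == dim(truth$labels)))
    cellseg_stop("cellseg_param_error", "label maps differ in shape")
  if (iou_min <= 0 || iou_min >= 1)
    cellseg_stop("cellseg_param_error", "iou_min must be in (0, 1)")
  np <- pred$n_components; nt <- truth$n_components

  any_fg <- pred$labels > 0L | truth$labels > 0L
  p <- pred$labels[any_fg]; t <- truth$labels[any_fg]
  ov <- table(factor(t, levels = 0:nt), factor(p, levels = 0:np))
  ov <- matrix(as.numeric(ov), nt + 1, np + 1)  # rows: truth 0..nt, cols: pred 0..np
  area_t <- rowSums(ov)[-1]
  area_p <- colSums(ov)[-1]

  overseg <- underseg <- overdetect <- matched <- 0L
  claims <- integer(np)   # truth cell majority-owning each prediction (0 = none)
  if (np > 0) {
    inter <- ov[-1, -1, drop = FALSE]
    if (nt == 0) {
      overdetect <- np
    } else {
      for (j in seq_len(np)) {
        best <- which.max(inter[, j])
        if (inter[best, j] > area_p[j] / 2) claims[j] <- best
        if (max(inter[, j]) == 0) overdetect <- overdetect + 1L
      }
    }
    if (nt > 0) {
      k_per_truth <- tabulate(claims[claims > 0L], nbins = nt)
      overseg <- sum(pmax(k_per_truth - 1L, 0L))
      covers_per_pred <- vapply(seq_len(np), function(j)
        sum(inter[, j] > area_t / 2), integer(1))
      underseg <- sum(pmax(covers_per_pred - 1L, 0L))
      # one-to-one matches at the IoU floor
      for (tt in which(k_per_truth == 1L)) {
        j <- which(claims == tt)[1]
        iou <- inter[tt, j] / (area_t[tt] + area_p[j] - inter[tt, j])
        if (iou >= iou_min) matched <- matched + 1L
      }
    }
  }
  rates <- list(
    overseg = if (nt) overseg / nt else NA_real_,
    underseg = if (nt) underseg / nt else NA_real_,
    overdetect = if (nt) overdetect / nt else NA_real_,
    overall = if (nt) (overseg + underseg + overdetect) / nt else NA_real_)
  structure(list(n_truth = nt, n_pred = np, n_matched = matched,
                 n_overseg_events = overseg, n_underseg_events = underseg,
                 n_overdetect = overdetect, rates = rates),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %d truth / %d pred; matched %d; overseg %d (%.1f%%), underseg %d (%.1f%%), overdetect %d (%.1f%%), overall %.1f%%>\n",
    x$n_truth, x$n_pred, x$n_matched,
    x$n_overseg_events, 100 * x$rates$overseg,
    x$n_underseg_events, 100 * x$rates$underseg,
    x$n_overdetect, 100 * x$rates$overdetect,
    100 * x$rates$overall))
  invisible(x)
}
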