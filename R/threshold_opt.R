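# Operating-point calibration: pick the IoU threshold from the behaviour of
# LAMR across an IoU grid, then pick the deployment confidence threshold by
# maximising F1 (classification view) and by minimising count MAPE
# (regression view). The two optima generally differ, which is the point:
# counting tolerates individual mistakes as long as false and missed
# detections cancel.

#' Pick the operating IoU threshold from a LAMR-vs-IoU profile
#'
#' LAMR is flat while the IoU threshold is loose and rises sharply past a
#' knee; the knee is the best operating point (tightest localisation without
#' paying in miss rate). The knee is operationalised as the largest grid
#' value whose LAMR is within `delta` (absolute) of the minimum over the
#' grid.
#'
#' @param lamr_by_iou LAMR values aligned with `iou_grid`.
#' @param iou_grid ascending IoU thresholds (at least 2).
#' @param delta absolute LAMR tolerance defining "still flat" (default 0.02).
#' @return the chosen IoU threshold (an element of `iou_grid`).
#' @export
#' @examples
#' choose_iou(c(0.19, 0.19, 0.19, 0.20, 0.20, 0.45, 0.80),
#'            c(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.90)) # 0.65
choose_iou <- function(lamr_by_iou, iou_grid, delta = 0.02) {
  if (length(iou_grid) < 2L) stop("iou_grid must have at least 2 values", call. = FALSE)
  if (is.unsorted(iou_grid, strictly = TRUE)) {
    stop("iou_grid must be strictly ascending", call. = FALSE)
  }
  if (length(lamr_by_iou) != length(iou_grid)) {
    stop("lamr_by_iou and iou_grid must align", call. = FALSE)
  }
  ok <- which(lamr_by_iou <= min(lamr_by_iou) + delta)
  iou_grid[max(ok)]
}

#' Sweep the IoU threshold grid and pick the operating value
#'
#' Computes the confidence-swept MR-FPPI curve and its LAMR at each IoU
#' threshold of the grid, then applies [choose_iou()]. The default grid is
#' the customary 0.05/0.20/0.35/0.50/0.65/0.80/0.90 ladder.
#'
#' @param x an [image_set()].
#' @param iou_grid ascending IoU thresholds.
#' @param delta tolerance passed to [choose_iou()].
#' @param log_average passed to [lamr()].
#' @return list with `iou_grid`, `lamr_by_iou`, `chosen_iou`, `delta`.
#' @export
sweep_iou <- function(x, iou_grid = c(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.90),
                      delta = 0.02, log_average = FALSE) {
  if (length(iou_grid) < 2L) stop("iou_grid must have at least 2 values", call. = FALSE)
  lamr_by_iou <- vapply(iou_grid, function(t) {
    mr_fppi_curve(x, iou_threshold = t, log_average = log_average)$lamr
  }, numeric(1))
  list(iou_grid = iou_grid, lamr_by_iou = lamr_by_iou,
       chosen_iou = choose_iou(lamr_by_iou, iou_grid, delta), delta = delta)
}

#' Sweep the confidence threshold for F1 and count MAPE
#'
#' Evaluates every confidence cut on the grid `{0, step, ..., 1}`. F1 comes
#' from greedy matching at `iou_threshold`; the per-image count estimate
#' `ES_i` feeding MAPE is the raw number of detections above the cut (no
#' matching -- deployment counting has no ground truth to match against).
#' Reports the argmax of F1 and the argmin of MAPE, ties broken toward the
#' higher threshold (fewer false positives at equal metric).
#'
#' @param x an [image_set()].
#' @param iou_threshold IoU used for the F1 matching.
#' @param conf_step grid step in (0, 0.5\]; the default 0.01 gives
#'   two-decimal thresholds.
#' @return an object of class `"confidence_sweep"`: list with `conf_grid`,
#'   `f1_by_conf`, `mape_by_conf`, `best_f1` and `best_mape` (each
#'   `list(value, threshold)`), `iou_threshold`, `n_images_excluded` (images
#'   with zero ground truth, excluded from MAPE).
#' @export
sweep_confidence <- function(x, iou_threshold = 0.5, conf_step = 0.01) {
  stopifnot_scalar_number(conf_step, "conf_step", lo = 1e-6, hi = 0.5)
  conf_grid <- seq(0, 1, by = conf_step)
  n_gt <- nrow(x$ground_truth)
  if (!n_gt) stop("confidence sweep needs ground truth", call. = FALSE)
  sweep <- sweep_matches(x, iou_threshold)
  gt_i <- gt_counts(x)
  use <- gt_i > 0
  if (!any(use)) stop("all images have zero ground truth", call. = FALSE)
  # counts of detections (and matched detections) with confidence >= c,
  # via one pass over the descending-confidence sweep
  f1_by_conf <- numeric(length(conf_grid))
  mape_by_conf <- numeric(length(conf_grid))
  cum_tp <- cumsum(!is.na(sweep$gt_row))
  det <- x$detections
  ids <- x$images$image_id
  img_f <- factor(det$image_id, levels = ids)
  for (i in seq_along(conf_grid)) {
    cc <- conf_grid[i]
    k <- sum(sweep$confidence >= cc)
    tp <- if (k) cum_tp[k] else 0L
    fp <- k - tp
    fn <- n_gt - tp
    f1_by_conf[i] <- if (tp > 0) 2 * tp / (2 * tp + fp + fn) else 0
    es_i <- as.integer(table(img_f[det$confidence >= cc]))
    mape_by_conf[i] <- mean(abs(es_i[use] - gt_i[use]) / gt_i[use])
  }
  pick_hi <- function(idx) max(idx) # ties toward higher threshold
  bf <- pick_hi(which(f1_by_conf == max(f1_by_conf)))
  bm <- pick_hi(which(mape_by_conf == min(mape_by_conf)))
  structure(list(conf_grid = conf_grid,
                 f1_by_conf = f1_by_conf,
                 mape_by_conf = mape_by_conf,
                 best_f1 = list(value = f1_by_conf[bf], threshold = conf_grid[bf]),
                 best_mape = list(value = mape_by_conf[bm], threshold = conf_grid[bm]),
                 iou_threshold = iou_threshold,
                 n_images_excluded = sum(!use)),
            class = "confidence_sweep")
}

#' @export
print.confidence_sweep <- function(x, ...) {
  cat(sprintf("<confidence_sweep> IoU %.2f: best F1 %.4f @ %.2f, best MAPE %.4f @ %.2f\n",
              x$iou_threshold, x$best_f1$value, x$best_f1$threshold,
              x$best_mape$value, x$best_mape$threshold))
  invisible(x)
}

#' Full threshold-calibration report
#'
#' Convenience wrapper: [sweep_iou()] to choose the IoU threshold, then
#' [sweep_confidence()] at the chosen IoU.
#'
#' @inheritParams sweep_iou
#' @inheritParams sweep_confidence
#' @return an object of class `"threshold_report"` combining both sweeps.
#' @export
optimize_thresholds <- function(x,
                                iou_grid = c(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.90),
                                conf_step = 0.01, delta = 0.02,
                                log_average = FALSE) {
  iou <- sweep_iou(x, iou_grid = iou_grid, delta = delta,
                   log_average = log_average)
  conf <- sweep_confidence(x, iou_threshold = iou$chosen_iou,
                           conf_step = conf_step)
  structure(c(iou, unclass(conf)), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> chosen IoU %.2f; best F1 %.4f @ conf %.2f; best MAPE %.4f @ conf %.2f\n",
              x$chosen_iou, x$best_f1$value, x$best_f1$threshold,
              x$best_mape$value, x$best_mape$threshold))
  invisible(x)
}
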