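# Count-regression metrics: false positives per image (FPPI), miss rate
# (MR = 1 - recall), the MR-FPPI curve swept over the confidence threshold,
# its log-average summary (LAMR), and the mean absolute percentage error of
# per-image counts (MAPE). MR/FPPI replace precision/recall when the task is
# counting rather than classification: surveys tolerate a bounded number of
# false detections per image regardless of object density.

#' FPPI and miss rate from a match result
#'
#' `fppi = FP / N` with `N` the number of images (including images without
#' ground truth); `mr = FN / GT = 1 - recall`. With no ground truth the miss
#' rate is undefined and returned as `NA`.
#'
#' @param m a [match_detections()] result (or list with `tp`, `fp`, `fn`).
#' @param n_images number of images `N`; defaults to the count recorded in
#'   `m`.
#' @return list with `fppi` and `mr`.
#' @export
#' @examples
#' fppi_mr(list(tp = 45, fp = 10, fn = 5), n_images = 10)
fppi_mr <- function(m, n_images = m$n_images) {
  stopifnot_scalar_number(n_images, "n_images", lo = 1)
  n_gt <- m$tp + m$fn
  mr <- if (n_gt > 0) m$fn / n_gt else NA_real_
  list(fppi = m$fp / n_images, mr = mr)
}

#' Miss-rate vs FPPI curve over the confidence sweep
#'
#' Varies the confidence threshold over every distinct detection confidence
#' (descending) with greedy matching fixed at `iou_threshold`; each threshold
#' yields one (FPPI, MR) point. The result is intrinsically a step function:
#' FPPI is non-decreasing and MR non-increasing as the threshold drops.
#'
#' @inheritParams match_detections
#' @param log_average passed to [lamr()] for the curve's summary value.
#' @return an object of class `"mr_fppi_curve"`: list with `thresholds`
#'   (descending), aligned `fppi` and `mr`, `n_images`, and `lamr`.
#' @export
mr_fppi_curve <- function(x, iou_threshold = 0.5, log_average = FALSE) {
  if (!nrow(x$ground_truth)) {
    stop("MR-FPPI curve needs at least one ground-truth box", call. = FALSE)
  }
  n <- n_images(x)
  n_gt <- nrow(x$ground_truth)
  sweep <- sweep_matches(x, iou_threshold)
  if (!nrow(sweep)) {
    curve <- structure(list(thresholds = 1, fppi = 0, mr = 1,
                            n_images = n, lamr = NA_real_),
                       class = "mr_fppi_curve")
    curve$lamr <- lamr(curve, log_average = log_average)
    return(curve)
  }
  cum_tp <- cumsum(!is.na(sweep$gt_row))
  cum_fp <- cumsum(is.na(sweep$gt_row))
  last <- which(!duplicated(sweep$confidence, fromLast = TRUE))
  curve <- structure(list(thresholds = sweep$confidence[last],
                          fppi = cum_fp[last] / n,
                          mr = 1 - cum_tp[last] / n_gt,
                          n_images = n, lamr = NA_real_),
                     class = "mr_fppi_curve")
  curve$lamr <- lamr(curve, log_average = log_average)
  curve
}

#' @export
print.mr_fppi_curve <- function(x, ...) {
  cat(sprintf("<mr_fppi_curve> %d point(s), LAMR = %.4f\n",
              length(x$thresholds), x$lamr))
  invisible(x)
}

#' Log-average miss rate (LAMR)
#'
#' Averages the miss rate at nine FPPI reference rates evenly spaced in log
#' space over \[1e-2, 1e0\] (`10^(-2 + 0.25 k)`, k = 0..8). The curve is read
#' as a step function: each reference takes the MR of the largest achieved
#' FPPI at or below it; for references beyond the curve's largest FPPI this is
#' the minimum MR the curve achieves, and for references below its smallest
#' FPPI the first (highest-threshold) MR is used.
#'
#' By default the nine miss rates are averaged arithmetically. The pedestrian
#' -detection convention of averaging in log space (geometric mean) is
#' available with `log_average = TRUE`; the two differ numerically, so the
#' choice is explicit.
#'
#' @param curve an [mr_fppi_curve()], or any list with numeric `fppi` and
#'   `mr` ordered by descending threshold.
#' @param log_average average `log(MR)` instead of MR (MR floored at 1e-10).
#' @return scalar LAMR in \[0, 1\].
#' @export
lamr <- function(curve, log_average = FALSE) {
  fppi <- curve$fppi
  mr <- curve$mr
  if (!length(fppi) || length(fppi) != length(mr)) {
    stop("curve must have aligned, non-empty fppi and mr", call. = FALSE)
  }
  refs <- 10^(-2 + 0.25 * (0:8))
  at <- vapply(refs, function(r) {
    ok <- which(fppi <= r)
    if (length(ok)) mr[max(ok)] else mr[1L]
  }, numeric(1))
  if (log_average) exp(mean(log(pmax(at, 1e-10)))) else mean(at)
}

#' Mean absolute percentage error of per-image counts
#'
#' `MAPE = mean(|ES_i - GT_i| / GT_i)` over the images with a positive
#' ground-truth count (the denominator excludes images without objects; how
#' many were excluded is reported). This is the count-regression criterion
#' used to pick a deployment confidence threshold.
#'
#' @param estimate per-image estimated counts.
#' @param truth per-image ground-truth counts (same length).
#' @return list with `mape` (fraction), `mape_percent`, `n_used`,
#'   `n_excluded`.
#' @export
#' @examples
#' mape(c(12, 8, 10), c(10, 10, 10)) # 0.1333...
mape <- function(estimate, truth) {
  if (length(estimate) != length(truth)) {
    stop("`estimate` and `truth` must have equal length", call. = FALSE)
  }
  if (any(truth < 0) || any(estimate < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  use <- truth > 0
  if (!any(use)) stop("all ground-truth counts are zero; MAPE undefined",
                      call. = FALSE)
  value <- mean(abs(estimate[use] - truth[use]) / truth[use])
  list(mape = value, mape_percent = 100 * value,
       n_used = sum(use), n_excluded = sum(!use))
}

#' Per-image estimated counts at a confidence cut
#'
#' The raw number of detections with confidence at or above the cut in each
#' image -- no matching involved, because deployment counting has no ground
#' truth to match against. This is the `ES_i` series that count MAPE
#' evaluates.
#'
#' @param x an [image_set()].
#' @param confidence_threshold the cut.
#' @return integer vector aligned with `x$images$image_id`.
#' @export
counts_at_confidence <- function(x, confidence_threshold) {
  ids <- x$images$image_id
  det <- x$detections
  keep <- det$confidence >= confidence_threshold
  as.integer(table(factor(det$image_id[keep], levels = ids)))
}

#' Per-image ground-truth counts
#'
#' @param x an [image_set()].
#' @return integer vector aligned with `x$images$image_id`.
#' @export
gt_counts <- function(x) {
  as.integer(table(factor(x$ground_truth$image_id, levels = x$images$image_id)))
}
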