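# Detection <-> ground-truth matching and the classification metrics built on
# it. Matching is the de-facto standard greedy scheme: detections are
# processed in descending confidence and each claims the not-yet-matched
# ground-truth box with the highest IoU, provided that IoU reaches the
# threshold. TP/FP/FN counts depend on this choice, so it is stated here and
# in the documentation rather than left implicit. A useful consequence of the
# greedy order is that the matching at confidence cut c is exactly the prefix
# of the full sweep restricted to detections with confidence >= c, which lets
# PR and MR-FPPI curves be computed from a single pass.

# Full greedy sweep at one IoU threshold. Returns one row per detection in
# global processing order (confidence descending, ties by original row):
# det_row (row in x$detections), image_id, confidence, gt_row (row in
# x$ground_truth or NA when the detection is a false positive).
sweep_matches <- function(x, iou_threshold) {
  stopifnot(inherits(x, "image_set"))
  stopifnot_scalar_number(iou_threshold, "iou_threshold", lo = 1e-12, hi = 1)
  det <- x$detections
  gt <- x$ground_truth
  ord <- order(-det$confidence, seq_len(nrow(det)))
  res <- data.frame(det_row = ord,
                    image_id = det$image_id[ord],
                    confidence = det$confidence[ord],
                    gt_row = rep(NA_integer_, length(ord)),
                    stringsAsFactors = FALSE)
  if (!nrow(det) || !nrow(gt)) return(res)
  gt_by_image <- split(seq_len(nrow(gt)), gt$image_id)
  det_by_image <- split(seq_len(nrow(res)), res$image_id)
  gt_m <- as_box_matrix(gt)
  det_m <- as_box_matrix(det)
  for (img in names(det_by_image)) {
    g_idx <- gt_by_image[[img]]
    if (is.null(g_idx)) next
    free <- rep(TRUE, length(g_idx))
    iou <- iou_matrix(det_m[res$det_row[det_by_image[[img]]], , drop = FALSE],
                      gt_m[g_idx, , drop = FALSE])
    for (k in seq_along(det_by_image[[img]])) {
      if (!any(free)) break
      cand <- iou[k, ]
      cand[!free] <- -1
      best <- max(cand)
      if (best >= iou_threshold) {
        # ties between equal IoUs resolved toward the lower ground-truth index
        j <- which(cand == best)[1L]
        free[j] <- FALSE
        res$gt_row[det_by_image[[img]][k]] <- g_idx[j]
      }
    }
  }
  res
}

#' Match detections to ground truth at fixed thresholds
#'
#' Applies greedy confidence-descending matching per image: a detection with
#' confidence at or above `confidence_threshold` claims the unmatched
#' ground-truth box of its image with the highest IoU when that IoU reaches
#' `iou_threshold`. Each ground truth and each detection is matched at most
#' once; ties are broken deterministically (equal IoU: lower ground-truth row;
#' equal confidence: earlier detection row).
#'
#' @param x an [image_set()].
#' @param iou_threshold IoU required for a detection to claim a ground truth
#'   (in (0, 1\]).
#' @param confidence_threshold detections below this confidence are discarded
#'   before matching.
#' @return an object of class `"match_result"`: list with integer counts
#'   `tp`, `fp`, `fn`, the matched index pairs `tp_pairs` (rows into
#'   `x$detections` / `x$ground_truth`), a `per_image` data.frame, and the
#'   thresholds used.
#' @export
match_detections <- function(x, iou_threshold = 0.5, confidence_threshold = 0) {
  stopifnot_scalar_number(confidence_threshold, "confidence_threshold", 0, 1)
  sweep <- sweep_matches(x, iou_threshold)
  kept <- sweep[sweep$confidence >= confidence_threshold, , drop = FALSE]
  gt <- x$ground_truth
  tp <- sum(!is.na(kept$gt_row))
  fp <- nrow(kept) - tp
  fn <- nrow(gt) - tp
  ids <- x$images$image_id
  tp_img <- table(factor(kept$image_id[!is.na(kept$gt_row)], levels = ids))
  fp_img <- table(factor(kept$image_id[is.na(kept$gt_row)], levels = ids))
  gt_img <- table(factor(gt$image_id, levels = ids))
  per_image <- data.frame(image_id = ids,
                          tp = as.integer(tp_img),
                          fp = as.integer(fp_img),
                          fn = as.integer(gt_img) - as.integer(tp_img),
                          stringsAsFactors = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tp_pairs = data.frame(det_row = kept$det_row[!is.na(kept$gt_row)],
                                       gt_row = kept$gt_row[!is.na(kept$gt_row)]),
                 per_image = per_image,
                 n_images = nrow(x$images),
                 iou_threshold = iou_threshold,
                 confidence_threshold = confidence_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> IoU >= %.2f, conf >= %.2f: TP %d, FP %d, FN %d\n",
              x$iou_threshold, x$confidence_threshold, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP / (FP + TP)`, `recall = TP / (FN + TP)`, `f1` their
#' harmonic mean. Degenerate denominators are flagged rather than thrown:
#' with no detections precision is `NA` (undefined) and F1 is 0; with no
#' ground truth recall is `NA`.
#'
#' @param m a [match_detections()] result, or a list with `tp`, `fp`, `fn`.
#' @return list with `precision`, `recall`, `f1`, and logical
#'   `precision_defined`, `recall_defined`.
#' @export
#' @examples
#' precision_recall_f1(list(tp = 8, fp = 2, fn = 2))
precision_recall_f1 <- function(m) {
  tp <- m$tp
  fp <- m$fp
  fn <- m$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision_defined <- (tp + fp) > 0
  recall_defined <- (tp + fn) > 0
  precision <- if (precision_defined) tp / (tp + fp) else NA_real_
  recall <- if (recall_defined) tp / (tp + fn) else NA_real_
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       precision_defined = precision_defined, recall_defined = recall_defined)
}

#' Precision-recall curve and average precision
#'
#' Sweeps the confidence threshold over every distinct detection confidence
#' (descending) with greedy matching at `iou_threshold`, and integrates the
#' all-point interpolated precision envelope over recall to obtain AP. With a
#' single object class, mAP equals AP.
#'
#' @inheritParams match_detections
#' @return an object of class `"pr_curve"`: list with `thresholds`
#'   (descending distinct confidences), aligned `precision` and `recall`
#'   vectors, and scalar `ap`.
#' @export
average_precision <- function(x, iou_threshold = 0.5) {
  if (!nrow(x$ground_truth)) {
    stop("average precision needs at least one ground-truth box", call. = FALSE)
  }
  sweep <- sweep_matches(x, iou_threshold)
  if (!nrow(sweep)) {
    warning("no detections: AP is 0", call. = FALSE)
    return(structure(list(thresholds = numeric(), precision = numeric(),
                          recall = numeric(), ap = 0), class = "pr_curve"))
  }
  n_gt <- nrow(x$ground_truth)
  cum_tp <- cumsum(!is.na(sweep$gt_row))
  k <- seq_len(nrow(sweep))
  # curve points at distinct thresholds only (>= threshold semantics), so the
  # curve -- and AP -- is invariant under duplicating every image
  last <- which(!duplicated(sweep$confidence, fromLast = TRUE))
  thresholds <- sweep$confidence[last]
  precision <- cum_tp[last] / k[last]
  recall <- cum_tp[last] / n_gt
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, ap = ap),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d point(s), AP = %.4f\n", length(x$thresholds), x$ap))
  invisible(x)
}
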