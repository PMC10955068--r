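# Regional count validation and the flight-height / image-resolution
# workflow. The survey design question -- how high may the aircraft fly
# before burrow entrances stop being distinguishable from dung and shadows --
# is answered by comparing a field count (ground truth, GT) with a count made
# by visual interpretation of the image (image truth, IT) at each candidate
# height, scored with precision/recall/F1; the ground sample distance
# calculator converts heights to cm-per-pixel resolution.

#' Validate model counts against a reference series
#'
#' Computes the determination coefficient, RMSE, and count MAPE for paired
#' per-unit counts. The R-squared convention used here normalises the squared
#' error by the variance of the model series `x` (not of the reference):
#' `R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2)`. The conventional form
#' (denominator from the reference series `y`) is available via
#' `r2_reference = TRUE`; the two differ numerically. R2 can be negative; a
#' constant model series leaves it undefined (`NA`).
#'
#' @param x model counts per unit.
#' @param y reference counts per unit (same length, at least 2).
#' @param r2_reference use `sum((y - mean(y))^2)` as the R2 denominator.
#' @return an object of class `"count_validation"`: list with `r2`, `rmse`,
#'   `mape`, `mape_percent`, `n`, `r2_defined`.
#' @export
#' @examples
#' count_validation(c(1, 2, 3), c(1, 2, 4))$rmse # sqrt(1/3)
count_validation <- function(x, y, r2_reference = FALSE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired counts", call. = FALSE)
  sse <- sum((x - y)^2)
  denom <- if (r2_reference) sum((y - mean(y))^2) else sum((x - mean(x))^2)
  r2_defined <- denom > 0
  r2 <- if (r2_defined) 1 - sse / denom else NA_real_
  mp <- mape(x, y)
  structure(list(r2 = r2, rmse = sqrt(sse / n),
                 mape = mp$mape, mape_percent = mp$mape_percent,
                 n = n, r2_defined = r2_defined),
            class = "count_validation")
}

#' @export
print.count_validation <- function(x, ...) {
  cat(sprintf("<count_validation> n = %d: R2 = %.4f, RMSE = %.4f, MAPE = %.2f%%\n",
              x$n, x$r2, x$rmse, x$mape_percent))
  invisible(x)
}

#' Regional counting accuracy
#'
#' `(1 - |n_gt - n_est| / n_gt) * 100`: the percent agreement of a regional
#' total with the reference total; over- and under-counts of equal magnitude
#' are penalised equally.
#'
#' @param n_est estimated total count.
#' @param n_gt reference total count (> 0).
#' @return accuracy in percent (at most 100; negative if the estimate is
#'   more than twice the reference).
#' @export
#' @examples
#' regional_accuracy(110, 100) # 90
regional_accuracy <- function(n_est, n_gt) {
  stopifnot_scalar_number(n_est, "n_est", lo = 0)
  if (!is.numeric(n_gt) || length(n_gt) != 1L || n_gt <= 0) {
    stop("`n_gt` must be a single positive count", call. = FALSE)
  }
  (1 - abs(n_gt - n_est) / n_gt) * 100
}

#' Score one flight height of the resolution evaluation
#'
#' Takes the primitive counts of the visual-interpretation experiment --
#' field count `gt`, image-interpreted count `it`, and the `tp` of
#' interpreted burrows that are real -- and derives the scoreboard row:
#' `precision = tp / it`, `recall = tp / gt`, F1 their harmonic mean, with
#' `fp = it - tp` and `fn = gt - tp` for display, plus the image resolution
#' at the flight height from [gsd_cm_per_px()]. Values are rounded half-up to
#' 2 decimals for display (`precision`, `recall`, `f1`), with full precision
#' retained in `precision_exact` etc.
#'
#' @param gt field ground-truth count.
#' @param it image-truth (visual interpretation) count.
#' @param tp interpreted burrows that are real (`tp <= min(gt, it)`).
#' @param flight_height_m flight height in metres (optional, for the
#'   resolution column).
#' @param ... camera parameters passed to [gsd_cm_per_px()].
#' @return an object of class `"resolution_eval_row"` (a one-row list).
#' @export
#' @examples
#' resolution_eval(gt = 55, it = 53, tp = 53, flight_height_m = 30)
resolution_eval <- function(gt, it, tp, flight_height_m = NA, ...) {
  stopifnot_scalar_number(gt, "gt", lo = 0)
  stopifnot_scalar_number(it, "it", lo = 0)
  stopifnot_scalar_number(tp, "tp", lo = 0)
  if (tp > min(gt, it)) stop("tp cannot exceed min(gt, it)", call. = FALSE)
  precision <- if (it > 0) tp / it else NA_real_
  recall <- if (gt > 0) tp / gt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && tp > 0) {
    2 * precision * recall / (precision + recall)
  } else if (isTRUE(tp == 0)) 0 else NA_real_
  gsd <- if (is.na(flight_height_m)) NA_real_ else gsd_cm_per_px(flight_height_m, ...)
  structure(list(flight_height_m = flight_height_m,
                 gt = gt, it = it, tp = tp,
                 fp = it - tp, fn = gt - tp,
                 precision = round_half_up(precision, 2),
                 recall = round_half_up(recall, 2),
                 f1 = round_half_up(f1, 2),
                 precision_exact = precision, recall_exact = recall,
                 f1_exact = f1,
                 gsd_cm_per_px = gsd,
                 gsd_display = round_half_up(gsd, 1)),
            class = "resolution_eval_row")
}

#' @export
print.resolution_eval_row <- function(x, ...) {
  cat(sprintf("<resolution_eval> %s m (%.1f cm/px): GT %d, IT %d, TP %d -> P %.2f, R %.2f, F1 %.2f\n",
              format(x$flight_height_m), x$gsd_display, x$gt, x$it, x$tp,
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Ground sample distance from flight height and camera geometry
#'
#' Standard photogrammetric pinhole relation: one pixel covers
#' `height * pixel_pitch / focal_length` on the ground, i.e.
#' `gsd_cm = 100 * height_m * (sensor_width_mm / image_width_px) /
#' focal_length_mm`. Defaults describe a 45-megapixel full-frame camera
#' (36 mm sensor width, 8192 px image width, 35 mm lens); with them a 30 m
#' flight gives 0.38 cm/px, reported as 0.4 at one decimal. GSD is linear in
#' height.
#'
#' @param flight_height_m flight height above ground in metres.
#' @param sensor_width_mm physical sensor width in millimetres.
#' @param image_width_px image width in pixels.
#' @param focal_length_mm lens focal length in millimetres.
#' @return ground sample distance in cm per pixel.
#' @export
#' @examples
#' gsd_cm_per_px(30) # ~0.377
gsd_cm_per_px <- function(flight_height_m, sensor_width_mm = 36,
                          image_width_px = 8192, focal_length_mm = 35) {
  for (v in c("flight_height_m", "sensor_width_mm", "image_width_px",
              "focal_length_mm")) {
    stopifnot_scalar_number(get(v), v, lo = 1e-12)
  }
  100 * flight_height_m * (sensor_width_mm / image_width_px) / focal_length_mm
}
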