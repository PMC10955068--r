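# Box algebra for the whole toolkit.
#
# Boxes are axis-aligned rectangles in continuous pixel coordinates with the
# origin at the image top-left, x increasing rightward and y downward. The
# half-open convention [x_min, x_max) x [y_min, y_max) is used throughout so
# that adjacent tiles partition a scene without double-counting boundary
# pixels; areas and intersections are computed analytically, never on a
# raster.

#' Construct an axis-aligned box
#'
#' @param x_min,y_min,x_max,y_max pixel coordinates (continuous); must satisfy
#'   `x_max > x_min` and `y_max > y_min` (zero-area boxes are invalid
#'   geometry).
#' @return a named numeric vector of class `"box"`.
#' @export
#' @examples
#' box(0, 0, 2, 2)
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  check_boxes(rbind(b))
  class(b) <- "box"
  b
}

# Accept a box vector, an n x 4 matrix, or a data.frame with the four corner
# columns; return an n x 4 numeric matrix (x_min, y_min, x_max, y_max).
as_box_matrix <- function(b) {
  cols <- c("x_min", "y_min", "x_max", "y_max")
  if (is.data.frame(b)) {
    missing <- setdiff(cols, names(b))
    if (length(missing)) {
      stop("box data.frame lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(b[cols])
  } else if (is.matrix(b)) {
    m <- b[, 1:4, drop = FALSE]
  } else {
    m <- matrix(as.numeric(b), ncol = 4L)
  }
  colnames(m) <- cols
  storage.mode(m) <- "double"
  m
}

check_boxes <- function(m, what = "box") {
  if (any(!is.finite(m))) {
    stop(sprintf("invalid %s: non-finite coordinates", what), call. = FALSE)
  }
  bad <- m[, 3L] <= m[, 1L] | m[, 4L] <= m[, 2L]
  if (any(bad)) {
    stop(sprintf("invalid %s: zero or negative area (x_max <= x_min or y_max <= y_min) in row(s) %s",
                 what, paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(m)
}

#' Box areas
#'
#' @param b a box, n x 4 matrix, or data.frame with corner columns.
#' @return numeric vector of areas (pixels squared).
#' @export
box_area <- function(b) {
  m <- check_boxes(as_box_matrix(b))
  unname((m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L]))
}

# Pairwise intersection areas between two equal-length sets of boxes.
intersection_area <- function(a, b) {
  ix <- pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L])
  iy <- pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L])
  pmax(ix, 0) * pmax(iy, 0)
}

#' Intersection over union of two boxes
#'
#' The matching criterion used to decide whether a detection and an annotated
#' burrow entrance refer to the same object: intersection area divided by the
#' area of the union. Symmetric, 0 for disjoint boxes, 1 iff identical.
#'
#' @param a,b boxes (vectors, equal-length n x 4 matrices, or data.frames);
#'   when both have n rows the IoU is computed row-wise.
#' @return numeric vector in \[0, 1\].
#' @export
#' @examples
#' box_iou(box(0, 0, 2, 2), box(1, 0, 3, 2)) # 1/3
box_iou <- function(a, b) {
  ma <- check_boxes(as_box_matrix(a))
  mb <- check_boxes(as_box_matrix(b))
  stopifnot(nrow(ma) == nrow(mb))
  inter <- intersection_area(ma, mb)
  union <- box_area(ma) + box_area(mb) - inter
  unname(inter / union)
}

#' Intersection over the smaller box (IoS)
#'
#' Intersection area divided by the area of the smaller of the two boxes.
#' Near 1 when one box is (a truncated) re-detection of the other -- e.g. the
#' same burrow seen in two overlapping tiles -- while two adjacent but
#' distinct burrows keep a small IoS. This is what makes IoS a better
#' duplicate-suppression criterion than IoU for merged tile detections, and
#' the denominator `min(area(a), area(b))` makes suppression order-independent.
#'
#' @inheritParams box_iou
#' @return numeric vector in \[0, 1\]; 1 whenever the smaller box is fully
#'   contained in the larger.
#' @export
#' @examples
#' box_ios(box(0, 0, 10, 10), box(2, 2, 4, 4)) # 1: full containment
box_ios <- function(a, b) {
  ma <- check_boxes(as_box_matrix(a))
  mb <- check_boxes(as_box_matrix(b))
  stopifnot(nrow(ma) == nrow(mb))
  inter <- intersection_area(ma, mb)
  unname(inter / pmin(box_area(ma), box_area(mb)))
}

# Cross IoU matrix: rows of `a` vs rows of `b` -> nrow(a) x nrow(b).
iou_matrix <- function(a, b) {
  ma <- check_boxes(as_box_matrix(a))
  mb <- check_boxes(as_box_matrix(b))
  n <- nrow(ma)
  m <- nrow(mb)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  out <- matrix(0, n, m)
  area_a <- box_area(ma)
  area_b <- box_area(mb)
  for (j in seq_len(m)) {
    ix <- pmin(ma[, 3L], mb[j, 3L]) - pmax(ma[, 1L], mb[j, 1L])
    iy <- pmin(ma[, 4L], mb[j, 4L]) - pmax(ma[, 2L], mb[j, 2L])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}

# Cross IoS matrix, same layout as iou_matrix().
ios_matrix <- function(a, b) {
  ma <- check_boxes(as_box_matrix(a))
  mb <- check_boxes(as_box_matrix(b))
  n <- nrow(ma)
  m <- nrow(mb)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  out <- matrix(0, n, m)
  area_a <- box_area(ma)
  area_b <- box_area(mb)
  for (j in seq_len(m)) {
    ix <- pmin(ma[, 3L], mb[j, 3L]) - pmax(ma[, 1L], mb[j, 1L])
    iy <- pmin(ma[, 4L], mb[j, 4L]) - pmax(ma[, 2L], mb[j, 2L])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    out[, j] <- inter / pmin(area_a, area_b[j])
  }
  out
}

# Clip boxes (n x 4 matrix/data.frame) to a rectangle; rows that end up with
# zero or negative extent are returned with keep = FALSE.
clip_boxes <- function(b, x_min, y_min, x_max, y_max) {
  m <- as_box_matrix(b)
  m[, 1L] <- pmax(m[, 1L], x_min)
  m[, 2L] <- pmax(m[, 2L], y_min)
  m[, 3L] <- pmin(m[, 3L], x_max)
  m[, 4L] <- pmin(m[, 4L], y_max)
  keep <- m[, 3L] > m[, 1L] & m[, 4L] > m[, 2L]
  list(boxes = m, keep = keep)
}
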