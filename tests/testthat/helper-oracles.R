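# Independent oracles and fixture builders shared across the suite.

# Rasterization oracle for box overlap measures: counts covered unit cells on
# an integer grid (boxes must have integer coordinates). Deliberately naive
# and independent of the analytic implementation.
raster_overlap <- function(a, b) {
  cells <- function(bx) {
    xs <- seq(bx[1L], bx[3L] - 1L)
    ys <- seq(bx[2L], bx[4L] - 1L)
    outer(xs, ys * 100000, "+") # unique cell key
  }
  ca <- cells(a)
  cb <- cells(b)
  inter <- length(intersect(ca, cb))
  list(iou = inter / length(union(ca, cb)),
       ios = inter / min(length(ca), length(cb)))
}

# Brute-force LAMR: literal loop over the nine log-spaced FPPI references.
brute_lamr <- function(fppi, mr, log_average = FALSE) {
  vals <- numeric(9)
  for (k in 0:8) {
    ref <- 10^(-2 + 0.25 * k)
    best <- NA_real_
    best_fppi <- -Inf
    for (i in seq_along(fppi)) {
      if (fppi[i] <= ref && fppi[i] >= best_fppi) {
        best_fppi <- fppi[i]
        best <- mr[i]
      }
    }
    if (is.na(best)) best <- mr[1L]
    vals[k + 1L] <- best
  }
  if (log_average) exp(mean(log(pmax(vals, 1e-10)))) else mean(vals)
}

# Exhaustive maximum bipartite matching size: the optimal-assignment oracle
# for small instances (n_det, n_gt <= 6).
brute_max_matching <- function(iou, threshold) {
  n_det <- nrow(iou)
  n_gt <- ncol(iou)
  if (!n_det || !n_gt) return(0L)
  recur <- function(d, free_gt) {
    if (d > n_det) return(0L)
    best <- recur(d + 1L, free_gt) # leave detection d unmatched
    for (g in which(free_gt)) {
      if (iou[d, g] >= threshold) {
        f2 <- free_gt
        f2[g] <- FALSE
        best <- max(best, 1L + recur(d + 1L, f2))
      }
    }
    best
  }
  recur(1L, rep(TRUE, n_gt))
}

# Build a one-line image set from plain vectors.
make_set <- function(gt_boxes = NULL, det_boxes = NULL, det_conf = NULL,
                     image_id = "img1", images = NULL) {
  gt <- if (is.null(gt_boxes)) NULL else {
    m <- matrix(gt_boxes, ncol = 4L, byrow = TRUE)
    data.frame(image_id = image_id, x_min = m[, 1], y_min = m[, 2],
               x_max = m[, 3], y_max = m[, 4])
  }
  det <- if (is.null(det_boxes)) NULL else {
    m <- matrix(det_boxes, ncol = 4L, byrow = TRUE)
    data.frame(image_id = image_id, x_min = m[, 1], y_min = m[, 2],
               x_max = m[, 3], y_max = m[, 4], confidence = det_conf)
  }
  image_set(gt, det, images = images)
}

# Random integer-coordinate box within [0, lim]^2.
random_int_box <- function(lim = 20) {
  x <- sort(sample(0:lim, 2))
  y <- sort(sample(0:lim, 2))
  while (x[1] == x[2]) x <- sort(sample(0:lim, 2))
  while (y[1] == y[2]) y <- sort(sample(0:lim, 2))
  c(x[1], y[1], x[2], y[2])
}
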