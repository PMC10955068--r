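# Readers and writers for annotations and detections, plus the image-set
# container the metrics operate on and dataset-split arithmetic.

gt_columns <- c("image_id", "x_min", "y_min", "x_max", "y_max")
det_columns <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")

empty_gt <- function() {
  data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), label = character(),
             stringsAsFactors = FALSE)
}

empty_det <- function() {
  data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric(),
             stringsAsFactors = FALSE)
}

#' Read LabelMe rectangle annotations
#'
#' Parses LabelMe-dialect JSON files (one per image) and returns the rectangle
#' shapes as ground-truth boxes. The two diagonal points of each rectangle may
#' be given in any order; coordinates are normalised so that
#' `x_min < x_max` and `y_min < y_max`. Non-rectangle shapes are skipped with
#' a warning. The image id is taken from the file's `imagePath` field
#' (basename, extension stripped) and falls back to the JSON file name.
#'
#' @param paths character vector of file paths, or a single directory whose
#'   `*.json` files are all read.
#' @return a data.frame with columns `image_id`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `label`.
#' @export
read_labelme <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.json$", full.names = TRUE)
  }
  out <- lapply(paths, read_labelme_one)
  if (!length(out)) return(empty_gt())
  do.call(rbind, out)
}

read_labelme_one <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  image_id <- doc$imagePath %||% basename(path)
  image_id <- sub("\\.[A-Za-z0-9]+$", "", basename(image_id))
  shapes <- doc$shapes %||% list()
  rows <- lapply(seq_along(shapes), function(i) {
    sh <- shapes[[i]]
    type <- sh$shape_type %||% "rectangle"
    if (!identical(type, "rectangle")) {
      warning(sprintf("%s: shape %d has type '%s', not rectangle; skipped",
                      basename(path), i, type), call. = FALSE)
      return(NULL)
    }
    pts <- do.call(rbind, lapply(sh$points, unlist))
    if (is.null(pts) || nrow(pts) < 2L || ncol(pts) != 2L) {
      warning(sprintf("%s: shape %d has malformed points; skipped",
                      basename(path), i), call. = FALSE)
      return(NULL)
    }
    data.frame(image_id = image_id,
               x_min = min(pts[, 1L]), y_min = min(pts[, 2L]),
               x_max = max(pts[, 1L]), y_max = max(pts[, 2L]),
               label = as.character(sh$label %||% "object"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_gt())
  do.call(rbind, rows)
}

#' Write ground truth as a LabelMe-dialect JSON file
#'
#' One file per image id, written into `dir`. Used by the synthetic-survey
#' simulator so that generated truth round-trips through the same reader as
#' field annotations.
#'
#' @param gt ground-truth data.frame (`image_id`, corner columns, optional
#'   `label`).
#' @param dir output directory (created if absent).
#' @param image_width,image_height image dimensions recorded in the files.
#' @return invisibly, the paths written.
#' @export
write_labelme <- function(gt, dir, image_width = NA, image_height = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (id in unique(gt$image_id)) {
    g <- gt[gt$image_id == id, , drop = FALSE]
    shapes <- lapply(seq_len(nrow(g)), function(i) {
      list(label = if ("label" %in% names(g)) g$label[i] else "hole",
           points = list(c(g$x_min[i], g$y_min[i]), c(g$x_max[i], g$y_max[i])),
           shape_type = "rectangle")
    })
    doc <- list(version = "4.5.10", shapes = shapes,
                imagePath = paste0(id, ".jpg"),
                imageHeight = image_height, imageWidth = image_width)
    p <- file.path(dir, paste0(id, ".json"))
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read scored detections
#'
#' Supports two dialects: COCO detection-results JSON (an array of
#' `{image_id, category_id, bbox: [x, y, w, h], score}` records, `bbox` in
#' corner-plus-size convention) and CSV with header
#' `image_id,x_min,y_min,x_max,y_max,confidence`. Both are converted to the
#' corner convention. Confidences outside \[0, 1\] are clamped with a warning;
#' a COCO record with non-positive width or height is an error naming the
#' record.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.json` is COCO, `.csv` is CSV),
#'   `"coco"`, or `"csv"`.
#' @return a data.frame with columns `image_id`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `confidence`.
#' @export
read_detections <- function(path, format = c("auto", "coco", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
  }
  det <- if (format == "coco") read_detections_coco(path) else read_detections_csv(path)
  det$confidence <- clamp_confidence(det$confidence)
  if (nrow(det)) check_boxes(as_box_matrix(det), what = "detection box")
  det
}

clamp_confidence <- function(conf) {
  out_of_range <- conf < 0 | conf > 1
  if (any(out_of_range)) {
    warning(sprintf("%d confidence value(s) outside [0, 1] clamped",
                    sum(out_of_range)), call. = FALSE)
  }
  clamp(conf, 0, 1)
}

read_detections_coco <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(recs)) return(empty_det())
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    bb <- unlist(r$bbox)
    if (length(bb) != 4L) {
      stop(sprintf("record %d: bbox must have 4 elements", i), call. = FALSE)
    }
    if (bb[3L] <= 0 || bb[4L] <= 0) {
      stop(sprintf("record %d (image_id %s): non-positive bbox width/height",
                   i, as.character(r$image_id)), call. = FALSE)
    }
    data.frame(image_id = as.character(r$image_id),
               x_min = bb[1L], y_min = bb[2L],
               x_max = bb[1L] + bb[3L], y_max = bb[2L] + bb[4L],
               confidence = as.numeric(r$score),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(det_columns, names(df))
  if (length(missing)) {
    stop("detection CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$image_id <- as.character(df$image_id)
  df[det_columns]
}

#' Write scored detections
#'
#' Inverse of [read_detections()]; a write-then-read round trip reproduces
#' boxes and confidences exactly (CSV uses full double precision).
#'
#' @param det detection data.frame.
#' @param path output file.
#' @param format `"csv"` or `"coco"`.
#' @return invisibly, `path`.
#' @export
write_detections <- function(det, path, format = c("auto", "coco", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
  }
  if (format == "csv") {
    df <- det[det_columns]
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(det)), function(i) {
      list(image_id = det$image_id[i], category_id = 1L,
           bbox = c(det$x_min[i], det$y_min[i],
                    det$x_max[i] - det$x_min[i], det$y_max[i] - det$y_min[i]),
           score = det$confidence[i])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Bundle ground truth and detections into an image set
#'
#' The container every metric operates on: per-image ground-truth boxes and
#' scored detections, plus the roster of images. Images without any ground
#' truth still count towards the image total `N` used by false positives per
#' image. When image dimensions are supplied, boxes are clamped to
#' `[0, width] x [0, height]`; a box that falls entirely outside its image is
#' an error.
#'
#' @param ground_truth data.frame with `image_id` and corner columns.
#' @param detections data.frame with `image_id`, corner columns, `confidence`.
#' @param images optional data.frame with `image_id` and optionally `width`,
#'   `height`; defaults to the union of ids seen in `ground_truth` and
#'   `detections`.
#' @return an object of class `"image_set"` with elements `ground_truth`,
#'   `detections` (sorted by descending confidence), and `images`.
#' @export
image_set <- function(ground_truth = NULL, detections = NULL, images = NULL) {
  gt <- if (is.null(ground_truth) || !nrow(ground_truth)) empty_gt() else ground_truth
  det <- if (is.null(detections) || !nrow(detections)) empty_det() else detections
  gt$image_id <- as.character(gt$image_id)
  det$image_id <- as.character(det$image_id)
  if (nrow(det) && (any(det$confidence < 0) || any(det$confidence > 1))) {
    stop("detection confidences must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(images)) {
    images <- data.frame(image_id = unique(c(gt$image_id, det$image_id)),
                         width = NA_real_, height = NA_real_,
                         stringsAsFactors = FALSE)
  } else {
    images <- as.data.frame(images, stringsAsFactors = FALSE)
    images$image_id <- as.character(images$image_id)
    if (is.null(images$width)) images$width <- NA_real_
    if (is.null(images$height)) images$height <- NA_real_
    unknown <- setdiff(c(gt$image_id, det$image_id), images$image_id)
    if (length(unknown)) {
      stop("boxes reference image ids missing from `images`: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  gt <- clamp_to_image(gt, images, "ground-truth")
  det <- clamp_to_image(det, images, "detection")
  if (nrow(gt)) check_boxes(as_box_matrix(gt), "ground-truth box")
  if (nrow(det)) {
    check_boxes(as_box_matrix(det), "detection box")
    det <- det[order(-det$confidence), , drop = FALSE]
    rownames(det) <- NULL
  }
  structure(list(ground_truth = gt, detections = det, images = images),
            class = "image_set")
}

clamp_to_image <- function(boxes, images, what) {
  if (!nrow(boxes)) return(boxes)
  dims <- images[match(boxes$image_id, images$image_id), c("width", "height")]
  have <- !is.na(dims$width) & !is.na(dims$height)
  if (any(have)) {
    boxes$x_min[have] <- pmax(boxes$x_min[have], 0)
    boxes$y_min[have] <- pmax(boxes$y_min[have], 0)
    boxes$x_max[have] <- pmin(boxes$x_max[have], dims$width[have])
    boxes$y_max[have] <- pmin(boxes$y_max[have], dims$height[have])
    bad <- have & (boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min)
    if (any(bad)) {
      stop(sprintf("%d %s box(es) lie entirely outside their image",
                   sum(bad), what), call. = FALSE)
    }
  }
  boxes
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d image(s), %d ground-truth box(es), %d detection(s)\n",
              nrow(x$images), nrow(x$ground_truth), nrow(x$detections)))
  invisible(x)
}

#' Number of images in an image set
#' @param x an `image_set`.
#' @return integer count (the `N` of false positives per image).
#' @export
n_images <- function(x) {
  stopifnot(inherits(x, "image_set"))
  nrow(x$images)
}

#' Largest-remainder apportionment of n items by a ratio
#'
#' Splits `n` into integer parts proportional to `ratio`, assigning leftover
#' units to the largest fractional remainders (ties to the earlier component).
#' The parts always sum to `n`.
#'
#' @param n total count.
#' @param ratio non-negative weights, not all zero.
#' @return integer vector of the same length as `ratio`.
#' @export
#' @examples
#' apportion(6894, c(5, 2, 3)) # 3447 1379 2068
apportion <- function(n, ratio) {
  if (any(ratio < 0) || all(ratio == 0)) {
    stop("ratio components must be non-negative and not all zero", call. = FALSE)
  }
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(-(quota - base), seq_along(ratio))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Split image ids into train/validation/test sets
#'
#' Random (unstratified) shuffle followed by largest-remainder apportionment
#' of the id count by `ratio`; deterministic for a fixed seed. The survey
#' dataset convention is a 5:2:3 split.
#'
#' @param ids character or integer vector of unique ids.
#' @param ratio three non-negative weights (train, validation, test).
#' @param seed integer seed for the shuffle; `NULL` leaves the current RNG
#'   state in charge.
#' @return an object of class `"dataset_split"`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `sizes`, `ratio`.
#' @export
#' @examples
#' s <- split_dataset(paste0("img", 1:10), c(5, 2, 3), seed = 1)
#' s$sizes
split_dataset <- function(ids, ratio = c(5, 2, 3), seed = NULL) {
  if (length(ratio) != 3L) stop("`ratio` must have three components", call. = FALSE)
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  if (length(ids) < sum(ratio > 0)) {
    stop("fewer ids than nonzero ratio components", call. = FALSE)
  }
  sizes <- apportion(length(ids), ratio)
  perm <- with_seed(seed, sample(ids))
  ends <- cumsum(sizes)
  structure(list(train_ids = perm[seq_len(sizes[1L])],
                 val_ids = if (sizes[2L]) perm[(ends[1L] + 1L):ends[2L]] else ids[0],
                 test_ids = if (sizes[3L]) perm[(ends[2L] + 1L):ends[3L]] else ids[0],
                 sizes = sizes, ratio = ratio),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s -> train %d / val %d / test %d\n",
              paste(x$ratio, collapse = ":"),
              x$sizes[1L], x$sizes[2L], x$sizes[3L]))
  invisible(x)
}
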