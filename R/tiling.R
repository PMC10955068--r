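# Tile-grid planning and scene-level merging. Large survey frames (e.g.
# 8192 x 5460 px) are processed as overlapping tiles (e.g. 5 x 5 of
# 1708 x 1160); a burrow sitting on a tile seam is then detected in two or
# more tiles and must be de-duplicated after mapping detections back to the
# scene frame. Duplicates of a truncated re-detection have IoS close to 1
# while neighbouring distinct burrows keep a small IoS, so the suppression
# criterion is IoS, not IoU. The recommended overlap width is 2-3 times the
# typical box size.

#' Plan an overlapping tile grid
#'
#' Origins are evenly spaced with stride `floor((scene - tile) / (n - 1))`
#' and the final column/row clamped to end exactly at the scene border, so
#' the tiles cover the scene and adjacent tiles share an overlap band of
#' width `tile - stride`.
#'
#' @param scene_w,scene_h scene size in pixels.
#' @param tile_w,tile_h tile size in pixels (each no larger than the scene).
#' @param n_cols,n_rows grid dimensions.
#' @return an object of class `"tile_grid"`: list with the geometry fields
#'   and a `tiles` data.frame (`tile_id`, `col`, `row`, `origin_x`,
#'   `origin_y`), row-major.
#' @export
#' @examples
#' g <- plan_grid(8192, 5460, 1708, 1160, 5, 5)
#' g$stride_x # 1621
#' g$overlap_x # 87
plan_grid <- function(scene_w, scene_h, tile_w, tile_h, n_cols, n_rows) {
  for (v in c("scene_w", "scene_h", "tile_w", "tile_h", "n_cols", "n_rows")) {
    stopifnot_scalar_number(get(v), v, lo = 1)
  }
  if (tile_w > scene_w || tile_h > scene_h) {
    stop("tile must not exceed the scene", call. = FALSE)
  }
  if (n_cols * tile_w < scene_w) {
    stop(sprintf("cannot cover scene width %s with %d column(s) of width %s; need at least %d",
                 scene_w, n_cols, tile_w, ceiling(scene_w / tile_w)), call. = FALSE)
  }
  if (n_rows * tile_h < scene_h) {
    stop(sprintf("cannot cover scene height %s with %d row(s) of height %s; need at least %d",
                 scene_h, n_rows, tile_h, ceiling(scene_h / tile_h)), call. = FALSE)
  }
  origins <- function(scene, tile, n) {
    if (n == 1L) return(list(stride = 0, o = 0))
    stride <- floor((scene - tile) / (n - 1))
    o <- (seq_len(n) - 1) * stride
    o[n] <- scene - tile
    list(stride = stride, o = o)
  }
  ox <- origins(scene_w, tile_w, as.integer(n_cols))
  oy <- origins(scene_h, tile_h, as.integer(n_rows))
  tiles <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  tiles <- tiles[order(tiles$row, tiles$col), ]
  tiles <- data.frame(tile_id = seq_len(nrow(tiles)),
                      col = tiles$col, row = tiles$row,
                      origin_x = ox$o[tiles$col], origin_y = oy$o[tiles$row])
  structure(list(scene_width = scene_w, scene_height = scene_h,
                 tile_width = tile_w, tile_height = tile_h,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 stride_x = ox$stride, stride_y = oy$stride,
                 overlap_x = tile_w - ox$stride, overlap_y = tile_h - oy$stride,
                 tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %s x %s over %s x %s (overlap %s x %s px)\n",
              x$n_cols, x$n_rows, x$tile_width, x$tile_height,
              x$scene_width, x$scene_height, x$overlap_x, x$overlap_y))
  invisible(x)
}

#' Map tile-local detections to scene coordinates
#'
#' Translates boxes by the origin of the given tile; confidences are
#' unchanged. Boxes must lie within the tile bounds.
#'
#' @param dets data.frame of detections in tile-local coordinates.
#' @param grid a [plan_grid()] result.
#' @param tile_id the tile whose origin applies.
#' @return `dets` with translated corner columns.
#' @export
to_global <- function(dets, grid, tile_id) {
  stopifnot(inherits(grid, "tile_grid"))
  t <- grid$tiles[grid$tiles$tile_id == tile_id, , drop = FALSE]
  if (nrow(t) != 1L) stop("unknown tile_id: ", tile_id, call. = FALSE)
  if (!nrow(dets)) return(dets)
  m <- as_box_matrix(dets)
  eps <- 1e-9
  if (any(m[, 1L] < -eps | m[, 2L] < -eps |
          m[, 3L] > grid$tile_width + eps | m[, 4L] > grid$tile_height + eps)) {
    stop("detection box outside tile bounds", call. = FALSE)
  }
  dets$x_min <- dets$x_min + t$origin_x
  dets$x_max <- dets$x_max + t$origin_x
  dets$y_min <- dets$y_min + t$origin_y
  dets$y_max <- dets$y_max + t$origin_y
  dets
}

#' IoS-based non-maximum suppression
#'
#' Greedy suppression in descending confidence order (ties: earlier input row
#' first): a detection is dropped iff its IoS with an already-kept detection
#' exceeds `ios_threshold`. Because IoS uses the smaller box's area as the
#' denominator, a truncated fragment of a burrow re-detected in a
#' neighbouring tile scores IoS near 1 against the full box and is removed,
#' while two close but distinct burrows keep a small IoS and both survive.
#' Idempotent; with `ios_threshold = 1` only exact containments/duplicates
#' are suppressed.
#'
#' Ties on confidence are resolved toward the larger box (then input order):
#' among equal-confidence re-detections of one object, the most complete box
#' should win, or an orthogonally truncated fragment of the same object could
#' later survive against a kept sliver.
#'
#' @param dets detections in one global frame (data.frame with corner columns
#'   and `confidence`).
#' @param ios_threshold suppression threshold in (0, 1\] (default 0.5).
#' @return the kept detections, sorted by descending confidence.
#' @export
ios_nms <- function(dets, ios_threshold = 0.5) {
  stopifnot_scalar_number(ios_threshold, "ios_threshold", lo = 1e-9, hi = 1)
  if (!nrow(dets)) return(dets)
  ord <- order(-dets$confidence, -box_area(dets), seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  m <- check_boxes(as_box_matrix(d), "detection box")
  n <- nrow(d)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept_idx)) {
      ios <- ios_matrix(m[i, , drop = FALSE], m[kept_idx, , drop = FALSE])
      if (any(ios > ios_threshold)) next
    }
    keep[i] <- TRUE
    kept_idx <- c(kept_idx, i)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-tile detections into a scene count
#'
#' Maps every tile's detections to the scene frame, drops those below the
#' confidence threshold, removes duplicates with [ios_nms()], and counts what
#' remains. Confidence filtering happens before suppression (same result,
#' fewer comparisons).
#'
#' @param per_tile_dets data.frame with a `tile_id` column plus tile-local
#'   corner columns and `confidence`.
#' @param grid a [plan_grid()] result.
#' @param ios_threshold passed to [ios_nms()].
#' @param conf_threshold minimum confidence retained.
#' @return list with `detections` (merged, scene frame) and `count`.
#' @export
merge_and_count <- function(per_tile_dets, grid, ios_threshold = 0.5,
                            conf_threshold = 0) {
  stopifnot(inherits(grid, "tile_grid"))
  if (!nrow(per_tile_dets)) {
    return(list(detections = per_tile_dets, count = 0L))
  }
  if (!"tile_id" %in% names(per_tile_dets)) {
    stop("per_tile_dets needs a tile_id column", call. = FALSE)
  }
  pieces <- lapply(split(per_tile_dets, per_tile_dets$tile_id), function(d) {
    to_global(d, grid, d$tile_id[1L])
  })
  global <- do.call(rbind, pieces)
  global <- global[global$confidence >= conf_threshold, , drop = FALSE]
  merged <- ios_nms(global, ios_threshold = ios_threshold)
  rownames(merged) <- NULL
  list(detections = merged, count = nrow(merged))
}
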