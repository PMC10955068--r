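# Seeded synthetic-survey generator. Emulates the statistical structure of a
# spring steppe survey at ~0.4 cm/px: sub-image scenes of 1708 x 1160 px with
# a handful of small burrow entrances each (the survey dataset averaged about
# 3.6 per sub-image), optionally spatially clustered as burrow systems are, a
# detector that misses some burrows, jitters box corners and hallucinates
# clutter (dung, shadows), and Beta-shaped confidence distributions whose
# false-positive mass overlaps the true-positive tail -- the regime in which
# the F1-optimal and MAPE-optimal confidence cuts genuinely differ. No pixel
# imagery is ever rendered; the generator produces boxes, which is all the
# evaluation pipeline consumes.

#' Configuration of a synthetic survey scene
#'
#' @param scene_w,scene_h scene size in pixels (defaults: the survey
#'   sub-image size 1708 x 1160).
#' @param n_holes expected number of burrow entrances; drawn from a Poisson
#'   with this mean when `poisson = TRUE`, used as a fixed count otherwise.
#'   `NULL` with clustered placement means `n_parents * offspring_per_parent`.
#' @param poisson draw the count from a Poisson distribution.
#' @param placement `"uniform"` (complete spatial randomness) or
#'   `"clustered"` (parent-offspring aggregation: burrow systems).
#' @param n_parents,offspring_per_parent,cluster_radius_px clustered-mode
#'   parameters; offspring are displaced from their parent by isotropic
#'   Gaussian offsets with sd `cluster_radius_px`.
#' @param box_size_mean,box_size_cv mean box side in pixels and its
#'   coefficient of variation (a burrow entrance plus surrounding trampled
#'   trails spans roughly 40 px at 0.4 cm/px).
#' @param label_margin multiplicative enlargement (>= 1) applied to every
#'   box, emulating the labelling convention of drawing the rectangle out to
#'   the vole trails around the entrance rather than hugging the hole.
#' @param min_center_dist minimum distance between box centres in pixels
#'   (default: `box_size_mean`, so distinct burrows do not coincide).
#' @return a list of class `"scene_config"`.
#' @export
scene_config <- function(scene_w = 1708, scene_h = 1160,
                         n_holes = 3.6, poisson = TRUE,
                         placement = c("uniform", "clustered"),
                         n_parents = 3, offspring_per_parent = 4,
                         cluster_radius_px = 120,
                         box_size_mean = 40, box_size_cv = 0.15,
                         label_margin = 1,
                         min_center_dist = NULL) {
  placement <- match.arg(placement)
  if (label_margin < 1) stop("label_margin must be >= 1", call. = FALSE)
  if (is.null(n_holes)) {
    if (placement != "clustered") stop("n_holes is required for uniform placement", call. = FALSE)
    n_holes <- n_parents * offspring_per_parent
    poisson <- FALSE
  }
  structure(list(scene_w = scene_w, scene_h = scene_h,
                 n_holes = n_holes, poisson = poisson,
                 placement = placement,
                 n_parents = n_parents,
                 offspring_per_parent = offspring_per_parent,
                 cluster_radius_px = cluster_radius_px,
                 box_size_mean = box_size_mean, box_size_cv = box_size_cv,
                 label_margin = label_margin,
                 min_center_dist = min_center_dist %||% box_size_mean),
            class = "scene_config")
}

#' Generate one synthetic scene's ground truth
#'
#' Places burrow-entrance boxes in the scene per the configuration;
#' deterministic for a fixed seed. Box sides are Gaussian around
#' `box_size_mean` (floored at 30% of the mean), enlarged by `label_margin`,
#' and clamped inside the scene. Placement enforces the minimum
#' centre-distance by rejection; if the requested density cannot be placed
#' after bounded retries, an error is raised.
#'
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @param image_id id assigned to the scene's boxes.
#' @return a ground-truth data.frame (`image_id`, corner columns, `label`)
#'   with attributes `scene_w`, `scene_h`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1,
                           image_id = "scene") {
  stopifnot(inherits(config, "scene_config"))
  with_seed(seed, {
    n <- if (config$poisson) stats::rpois(1L, config$n_holes) else round(config$n_holes)
    gt <- empty_gt()
    if (n > 0) {
      centers <- place_centers(n, config)
      side <- pmax(stats::rnorm(n, config$box_size_mean,
                                config$box_size_cv * config$box_size_mean),
                   0.3 * config$box_size_mean)
      aspect <- exp(stats::rnorm(n, 0, 0.05))
      half_w <- side * sqrt(aspect) / 2 * config$label_margin
      half_h <- side / sqrt(aspect) / 2 * config$label_margin
      gt <- data.frame(image_id = image_id,
                       x_min = pmax(centers[, 1L] - half_w, 0),
                       y_min = pmax(centers[, 2L] - half_h, 0),
                       x_max = pmin(centers[, 1L] + half_w, config$scene_w),
                       y_max = pmin(centers[, 2L] + half_h, config$scene_h),
                       label = "hole", stringsAsFactors = FALSE)
    }
    attr(gt, "scene_w") <- config$scene_w
    attr(gt, "scene_h") <- config$scene_h
    gt
  })
}

place_centers <- function(n, config) {
  margin <- config$box_size_mean / 2
  lo_x <- margin; hi_x <- config$scene_w - margin
  lo_y <- margin; hi_y <- config$scene_h - margin
  if (hi_x <= lo_x || hi_y <= lo_y) stop("scene too small for box size", call. = FALSE)
  parents <- if (config$placement == "clustered") {
    cbind(stats::runif(config$n_parents, lo_x, hi_x),
          stats::runif(config$n_parents, lo_y, hi_y))
  } else NULL
  centers <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  max_tries <- 1000L * n
  while (nrow(centers) < n) {
    if (tries >= max_tries) {
      stop(sprintf("could not place %d boxes with min centre distance %s after %d tries; density infeasible",
                   n, config$min_center_dist, max_tries), call. = FALSE)
    }
    tries <- tries + 1L
    p <- if (is.null(parents)) {
      c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    } else {
      k <- sample.int(nrow(parents), 1L)
      clamp(parents[k, ] + stats::rnorm(2, 0, config$cluster_radius_px),
            c(lo_x, lo_y), c(hi_x, hi_y))
    }
    if (!nrow(centers) ||
        min(sqrt((centers[, 1L] - p[1L])^2 + (centers[, 2L] - p[2L])^2)) >=
          config$min_center_dist) {
      centers <- rbind(centers, p)
    }
  }
  centers
}

#' Configuration of the simulated detector's error structure
#'
#' @param p_detect probability that a true burrow is detected.
#' @param jitter_sd Gaussian sd (pixels) added independently to each box
#'   corner of a detected truth.
#' @param tp_conf_alpha,tp_conf_beta Beta shape of true-positive
#'   confidences (default Beta(8, 2): high-mode, mean 0.8).
#' @param fp_rate_per_image expected number of clutter false positives per
#'   image (Poisson), emulating burrow look-alikes such as dung.
#' @param fp_conf_alpha,fp_conf_beta Beta shape of false-positive
#'   confidences (default Beta(4, 4): mid-mode, its upper tail overlapping
#'   the true-positive distribution so that the F1-optimal and MAPE-optimal
#'   confidence cuts differ).
#' @param duplicate_in_overlap when the scene is tiled, emit a detection in
#'   every tile whose area contains it (creating the duplicates IoS-NMS must
#'   remove); `FALSE` assigns each detection only to the tile holding its
#'   centre.
#' @return a list of class `"detector_noise_config"`.
#' @export
detector_noise_config <- function(p_detect = 0.9, jitter_sd = 2,
                                  tp_conf_alpha = 8, tp_conf_beta = 2,
                                  fp_rate_per_image = 2,
                                  fp_conf_alpha = 4, fp_conf_beta = 4,
                                  duplicate_in_overlap = TRUE) {
  stopifnot_scalar_number(p_detect, "p_detect", 0, 1)
  stopifnot_scalar_number(jitter_sd, "jitter_sd", lo = 0)
  structure(list(p_detect = p_detect, jitter_sd = jitter_sd,
                 tp_conf_alpha = tp_conf_alpha, tp_conf_beta = tp_conf_beta,
                 fp_rate_per_image = fp_rate_per_image,
                 fp_conf_alpha = fp_conf_alpha, fp_conf_beta = fp_conf_beta,
                 duplicate_in_overlap = duplicate_in_overlap),
            class = "detector_noise_config")
}

#' Simulate detector output for known ground truth
#'
#' Each truth box is emitted with probability `p_detect`, its corners
#' jittered by Gaussian noise and its confidence drawn from the
#' true-positive Beta distribution; clutter false positives (count Poisson
#' per image, sized like typical truth boxes) are placed uniformly with
#' confidences from the false-positive Beta. Deterministic per seed.
#'
#' @param truths ground-truth data.frame (as from [generate_scene()]).
#' @param noise a [detector_noise_config()].
#' @param seed integer seed.
#' @param images optional data.frame (`image_id`, `width`, `height`) naming
#'   every image to simulate (so images without truth still receive clutter);
#'   defaults to the ids present in `truths` with the scene dimensions
#'   recorded by [generate_scene()].
#' @return a detection data.frame (`image_id`, corner columns,
#'   `confidence`).
#' @export
simulate_detector <- function(truths, noise = detector_noise_config(),
                              seed = 1, images = NULL) {
  stopifnot(inherits(noise, "detector_noise_config"))
  if (is.null(images)) {
    images <- data.frame(image_id = unique(truths$image_id),
                         width = attr(truths, "scene_w") %||% NA_real_,
                         height = attr(truths, "scene_h") %||% NA_real_,
                         stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    out <- list()
    # true positives
    if (nrow(truths)) {
      hit <- stats::runif(nrow(truths)) < noise$p_detect
      tt <- truths[hit, , drop = FALSE]
      if (nrow(tt)) {
        m <- as_box_matrix(tt) +
          matrix(stats::rnorm(4L * nrow(tt), 0, noise$jitter_sd), ncol = 4L)
        # jitter can invert an edge on tiny boxes; re-order the coordinates
        x1 <- pmin(m[, 1L], m[, 3L]); x2 <- pmax(m[, 1L], m[, 3L])
        y1 <- pmin(m[, 2L], m[, 4L]); y2 <- pmax(m[, 2L], m[, 4L])
        same <- x2 - x1 < 1 | y2 - y1 < 1
        x2[same] <- x1[same] + pmax(x2 - x1, 1)[same]
        y2[same] <- y1[same] + pmax(y2 - y1, 1)[same]
        out$tp <- data.frame(image_id = tt$image_id,
                             x_min = x1, y_min = y1, x_max = x2, y_max = y2,
                             confidence = stats::rbeta(nrow(tt),
                                                       noise$tp_conf_alpha,
                                                       noise$tp_conf_beta),
                             stringsAsFactors = FALSE)
      }
    }
    # clutter false positives, per image
    size_ref <- if (nrow(truths)) {
      mean(truths$x_max - truths$x_min)
    } else 40
    fp <- list()
    for (i in seq_len(nrow(images))) {
      n_fp <- stats::rpois(1L, noise$fp_rate_per_image)
      if (!n_fp) next
      w <- images$width[i]; h <- images$height[i]
      if (is.na(w) || is.na(h)) stop("image dimensions required to place clutter", call. = FALSE)
      side <- pmax(stats::rnorm(n_fp, size_ref, 0.2 * size_ref), 0.3 * size_ref)
      cx <- stats::runif(n_fp, side / 2, w - side / 2)
      cy <- stats::runif(n_fp, side / 2, h - side / 2)
      fp[[length(fp) + 1L]] <-
        data.frame(image_id = images$image_id[i],
                   x_min = cx - side / 2, y_min = cy - side / 2,
                   x_max = cx + side / 2, y_max = cy + side / 2,
                   confidence = stats::rbeta(n_fp, noise$fp_conf_alpha,
                                             noise$fp_conf_beta),
                   stringsAsFactors = FALSE)
    }
    out$fp <- if (length(fp)) do.call(rbind, fp) else NULL
    det <- do.call(rbind, out)
    if (is.null(det)) det <- empty_det()
    rownames(det) <- NULL
    det
  })
}

#' Simulate a multi-image survey as an image set
#'
#' Convenience wrapper: generates `n_scenes` independent scenes and their
#' detector output, each stage drawing from its own sub-stream of the master
#' seed (see [derive_seed()]), and bundles everything into an
#' [image_set()].
#'
#' @param n_scenes number of images to simulate.
#' @param config a [scene_config()].
#' @param noise a [detector_noise_config()].
#' @param seed master seed.
#' @return an `image_set`.
#' @export
simulate_survey <- function(n_scenes = 50, config = scene_config(),
                            noise = detector_noise_config(), seed = 1) {
  gt <- list()
  det <- list()
  for (i in seq_len(n_scenes)) {
    id <- sprintf("img%04d", i)
    g <- generate_scene(config, seed = derive_seed(seed, 2L * i), image_id = id)
    d <- simulate_detector(g, noise, seed = derive_seed(seed, 2L * i + 1L),
                           images = data.frame(image_id = id,
                                               width = config$scene_w,
                                               height = config$scene_h))
    gt[[i]] <- g
    det[[i]] <- d
  }
  image_set(do.call(rbind, gt), do.call(rbind, det),
            images = data.frame(image_id = sprintf("img%04d", seq_len(n_scenes)),
                                width = config$scene_w,
                                height = config$scene_h,
                                stringsAsFactors = FALSE))
}

#' Cut a scene's truth and detections into tile-local pieces
#'
#' Clips every box to each tile it intersects and emits it in tile-local
#' coordinates, so a box spanning an overlap band appears in two (or, at a
#' grid corner, four) tiles -- exactly the duplicated detections the IoS
#' merge must collapse. Truth fragments showing less than `min_visible` of
#' their full area in a tile are dropped from that tile's truth (an annotator
#' would not label a sliver); detection fragments are kept whenever they have
#' positive area. With `duplicate_in_overlap = FALSE` each detection is
#' instead assigned only to the first tile containing its centre.
#'
#' @param truth scene-frame ground-truth data.frame (single scene).
#' @param dets scene-frame detection data.frame.
#' @param grid a [plan_grid()] result.
#' @param min_visible minimum visible area fraction for truth fragments.
#' @param duplicate_in_overlap emit detections in every intersecting tile.
#' @return list with `truth` and `detections` data.frames, each carrying
#'   `tile_id`, a per-tile `image_id` of the form `<scene>_r<row>c<col>`, and
#'   tile-local corner columns.
#' @export
tile_scene <- function(truth, dets, grid, min_visible = 0.25,
                       duplicate_in_overlap = TRUE) {
  stopifnot(inherits(grid, "tile_grid"))
  scene_id <- unique(c(truth$image_id, dets$image_id))
  if (length(scene_id) > 1L) {
    stop("tile_scene expects a single scene; got ids: ",
         paste(scene_id, collapse = ", "), call. = FALSE)
  }
  if (!length(scene_id)) scene_id <- "scene"
  out_gt <- list()
  out_det <- list()
  det_center_x <- (dets$x_min + dets$x_max) / 2
  det_center_y <- (dets$y_min + dets$y_max) / 2
  det_assigned <- rep(FALSE, nrow(dets))
  for (k in seq_len(nrow(grid$tiles))) {
    t <- grid$tiles[k, ]
    tx0 <- t$origin_x; ty0 <- t$origin_y
    tx1 <- tx0 + grid$tile_width; ty1 <- ty0 + grid$tile_height
    tile_img <- sprintf("%s_r%dc%d", scene_id, t$row, t$col)
    if (nrow(truth)) {
      cl <- clip_boxes(truth, tx0, ty0, tx1, ty1)
      frac <- rep(0, nrow(truth))
      frac[cl$keep] <- box_area(cl$boxes[cl$keep, , drop = FALSE]) /
        box_area(truth[cl$keep, , drop = FALSE])
      keep <- cl$keep & frac >= min_visible
      if (any(keep)) {
        g <- truth[keep, , drop = FALSE]
        g[c("x_min", "y_min", "x_max", "y_max")] <-
          sweep(cl$boxes[keep, , drop = FALSE], 2L, c(tx0, ty0, tx0, ty0))
        g$image_id <- tile_img
        g$tile_id <- t$tile_id
        out_gt[[length(out_gt) + 1L]] <- g
      }
    }
    if (nrow(dets)) {
      cl <- clip_boxes(dets, tx0, ty0, tx1, ty1)
      keep <- cl$keep
      if (!duplicate_in_overlap) {
        center_in <- det_center_x >= tx0 & det_center_x < tx1 &
          det_center_y >= ty0 & det_center_y < ty1
        keep <- keep & center_in & !det_assigned
        det_assigned <- det_assigned | keep
      }
      if (any(keep)) {
        d <- dets[keep, , drop = FALSE]
        d[c("x_min", "y_min", "x_max", "y_max")] <-
          sweep(cl$boxes[keep, , drop = FALSE], 2L, c(tx0, ty0, tx0, ty0))
        d$image_id <- tile_img
        d$tile_id <- t$tile_id
        out_det[[length(out_det) + 1L]] <- d
      }
    }
  }
  gt <- if (length(out_gt)) do.call(rbind, out_gt) else cbind(empty_gt(), tile_id = integer())
  dd <- if (length(out_det)) do.call(rbind, out_det) else cbind(empty_det(), tile_id = integer())
  rownames(gt) <- NULL
  rownames(dd) <- NULL
  list(truth = gt, detections = dd)
}
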