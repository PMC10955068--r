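test_that("scene generation is seed-deterministic and respects the count", {
  cfg <- scene_config(n_holes = 5, poisson = FALSE)
  a <- generate_scene(cfg, seed = 42)
  b <- generate_scene(cfg, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 5L)
  c <- generate_scene(cfg, seed = 43)
  expect_false(identical(a, c))

  empty <- generate_scene(scene_config(n_holes = 0, poisson = FALSE), seed = 1)
  expect_equal(nrow(empty), 0L)

  # boxes stay inside the scene and apart
  big <- generate_scene(scene_config(n_holes = 30, poisson = FALSE), seed = 7)
  expect_true(all(big$x_min >= 0 & big$x_max <= 1708))
  expect_true(all(big$y_min >= 0 & big$y_max <= 1160))
  cx <- (big$x_min + big$x_max) / 2
  cy <- (big$y_min + big$y_max) / 2
  expect_gte(min(dist(cbind(cx, cy))), 40)

  expect_error(generate_scene(scene_config(scene_w = 200, scene_h = 200,
                                           n_holes = 60, poisson = FALSE),
                              seed = 1), "infeasible")
})

test_that("uniform placement is consistent with complete spatial randomness", {
  # mean nearest-neighbour distance of one generated scene against a
  # Monte-Carlo envelope from plain uniform sampling (the CSR oracle);
  # the min-distance constraint is negligible at this density
  cfg <- scene_config(scene_w = 5000, scene_h = 5000, n_holes = 500,
                      poisson = FALSE, box_size_mean = 20,
                      min_center_dist = 20)
  g <- generate_scene(cfg, seed = 31)
  cx <- (g$x_min + g$x_max) / 2
  cy <- (g$y_min + g$y_max) / 2
  nn_mean <- function(xy) {
    d <- as.matrix(dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  observed <- nn_mean(cbind(cx, cy))
  set.seed(99)
  env <- replicate(199, nn_mean(cbind(runif(500, 10, 4990),
                                      runif(500, 10, 4990))))
  expect_gte(observed, min(env))
  expect_lte(observed, max(env))
})

test_that("clustered placement aggregates relative to uniform", {
  base <- scene_config(scene_w = 5000, scene_h = 5000, n_holes = 200,
                       poisson = FALSE, box_size_mean = 20, min_center_dist = 20)
  clus <- scene_config(scene_w = 5000, scene_h = 5000, n_holes = 200,
                       poisson = FALSE, placement = "clustered",
                       n_parents = 5, cluster_radius_px = 150,
                       box_size_mean = 20, min_center_dist = 20)
  nn_mean <- function(g) {
    xy <- cbind((g$x_min + g$x_max) / 2, (g$y_min + g$y_max) / 2)
    d <- as.matrix(dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nn_mean(generate_scene(clus, seed = 5)),
            nn_mean(generate_scene(base, seed = 5)))
})

test_that("a noiseless detector reproduces the truth exactly", {
  cfg <- scene_config(n_holes = 6, poisson = FALSE)
  gt <- generate_scene(cfg, seed = 3, image_id = "img1")
  det <- simulate_detector(gt, detector_noise_config(p_detect = 1, jitter_sd = 0,
                                                     fp_rate_per_image = 0),
                           seed = 3)
  expect_equal(nrow(det), nrow(gt))
  expect_equal(det[c("x_min", "y_min", "x_max", "y_max")],
               gt[c("x_min", "y_min", "x_max", "y_max")])
  x <- image_set(gt, det)
  m <- match_detections(x, 0.5, min(det$confidence) - 1e-9)
  expect_equal(precision_recall_f1(m)$f1, 1)
  expect_equal(mape(counts_at_confidence(x, 0), gt_counts(x))$mape, 0)

  blind <- simulate_detector(gt, detector_noise_config(p_detect = 0,
                                                       fp_rate_per_image = 0),
                             seed = 3)
  expect_equal(nrow(blind), 0L)
  xb <- image_set(gt, blind)
  expect_equal(fppi_mr(match_detections(xb, 0.5, 0))$mr, 1)
})

test_that("realized detector error rates recover the configured parameters", {
  noise <- detector_noise_config(p_detect = 0.9, fp_rate_per_image = 2)
  for (seed in c(1, 2)) {
    x <- simulate_survey(200, scene_config(), noise, seed = seed)
    m <- match_detections(x, 0.5, 0)
    n_gt <- nrow(x$ground_truth)
    p_hat <- m$tp / n_gt
    expect_lte(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n_gt) + 0.01)
    fppi_hat <- fppi_mr(m)$fppi
    expect_lte(abs(fppi_hat - 2), 3 * sqrt(2 / 200) + 0.05)
  }
})

test_that("tiling emits boxes once per containing tile with truth-sliver drop", {
  g <- plan_grid(100, 100, 60, 60, 2, 2)
  # exclusive zone of tile 1 (x < 40): appears once
  inner <- data.frame(image_id = "s", x_min = 5, y_min = 5, x_max = 25,
                      y_max = 25, confidence = 0.9)
  t1 <- tile_scene(inner[1:5], inner, g)
  expect_equal(nrow(t1$detections), 1L)
  expect_equal(t1$detections$tile_id, 1L)

  # centred on the vertical seam inside the overlap band [40, 60): two tiles
  seam <- data.frame(image_id = "s", x_min = 42, y_min = 10, x_max = 58,
                     y_max = 26, confidence = 0.9)
  t2 <- tile_scene(seam[1:5], seam, g)
  expect_equal(nrow(t2$detections), 2L)
  expect_equal(sort(t2$detections$tile_id), c(1L, 2L))
  expect_equal(nrow(t2$truth), 2L)

  # a truth fragment below the visible-area floor is dropped from that tile
  edge <- data.frame(image_id = "s", x_min = 55, y_min = 10, x_max = 95,
                     y_max = 30, label = "hole")
  t3 <- tile_scene(edge, edge[0, ], g, min_visible = 0.25)
  # tile 1 sees 5/40 of the width (12.5% of area): dropped there
  expect_equal(t3$truth$tile_id, 2L)

  empty <- tile_scene(inner[1:5][0, ], inner[0, ], g)
  expect_equal(nrow(empty$detections), 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("centre assignment mode never duplicates a detection", {
  g <- plan_grid(100, 100, 60, 60, 2, 2)
  seam <- data.frame(image_id = "s", x_min = 42, y_min = 42, x_max = 58,
                     y_max = 58, confidence = 0.9)
  t <- tile_scene(seam[1:5], seam, g, duplicate_in_overlap = FALSE)
  expect_equal(nrow(t$detections), 1L)
})

test_that("the full pipeline returns the planted count with ample overlap", {
  for (seed in c(4, 12)) {
    cfg <- scene_config(scene_w = 1200, scene_h = 900, n_holes = 18,
                        poisson = FALSE, min_center_dist = 70)
    gt <- generate_scene(cfg, seed = seed, image_id = "s")
    det <- gt
    det$label <- NULL
    det$confidence <- 0.95
    g <- plan_grid(1200, 900, 400, 350, 4, 4)
    expect_gte(min(g$overlap_x, g$overlap_y), 2 * cfg$box_size_mean)
    tiled <- tile_scene(gt, det, g)
    expect_equal(merge_and_count(tiled$detections, g, 0.5)$count, nrow(gt))
  }
})

test_that("the MAPE-optimal cut is stable across seeds on 50-image surveys", {
  step <- 0.05
  th <- vapply(1:5, function(seed) {
    x <- simulate_survey(50, scene_config(), detector_noise_config(), seed = seed)
    sweep_confidence(x, 0.5, conf_step = step)$best_mape$threshold
  }, numeric(1))
  expect_lte(max(abs(th - median(th))), step + 1e-9)
})
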