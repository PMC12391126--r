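test_that("mask IoU matches hand-counted pixel sets and is symmetric", {
  a <- rect_mask(c(10, 10), 2, 2, 2, 2)
  expect_equal(mask_iou(a, a), 1)
  b <- rect_mask(c(10, 10), 6, 6, 2, 2)
  expect_equal(mask_iou(a, b), 0)
  # 2x2 squares offset by one column: intersection 2, union 6
  c2 <- rect_mask(c(10, 10), 3, 2, 2, 2)
  expect_equal(mask_iou(a, c2), 1 / 3)

  set.seed(9)
  for (i in 1:10) {
    x <- rect_mask(c(20, 20), sample(0:14, 1), sample(0:14, 1), 4, 3)
    y <- rect_mask(c(20, 20), sample(0:14, 1), sample(0:14, 1), 3, 5)
    expect_equal(mask_iou(x, y), mask_iou(y, x))
    expect_equal(mask_iou(x, y) == 1, identical(which(x > 0), which(y > 0)))
  }
  expect_error(mask_iou(matrix(0L, 5, 5), matrix(0L, 5, 5)), "both masks empty")
})

make_grid_frame <- function(jitter = 0, pitch = 100, size = 10,
                            dim = c(400, 400), seed = 1) {
  set.seed(seed)
  insts <- list()
  for (r in 0:3) for (c in 0:3) {
    x0 <- 50 + c * pitch + sample(seq(-jitter, jitter), 1)
    y0 <- 50 + r * pitch + sample(seq(-jitter, jitter), 1)
    insts <- c(insts, list(instance_mask(rect_mask(dim, x0, y0, size, size))))
  }
  insts
}

test_that("grid initialisation assigns row-major ids, robust to centroid jitter", {
  insts <- make_grid_frame(jitter = 0)
  expect_equal(assign_initial_ids(insts), 0:15)

  set.seed(2)
  shuffled <- sample(seq_along(insts))
  # instance i of the shuffled list is original instance shuffled[i],
  # whose row-major id is shuffled[i] - 1
  expect_equal(assign_initial_ids(insts[shuffled]), shuffled - 1L)

  # +/-5 px jitter at 100 px pitch does not change the assignment
  expect_equal(assign_initial_ids(make_grid_frame(jitter = 5)), 0:15)

  expect_error(assign_initial_ids(insts[1:15]), "expected 16 instances")
})

test_that("IoU inheritance keeps ids across frames and opens new tracks below threshold", {
  dim <- c(400, 400)
  f1 <- structure(list(time = parse_timestamp("2025-03-01-10-00-00"),
                       dim = dim, instances = make_grid_frame()),
                  class = "frame_observation")
  # identical second frame: all ids inherited
  f2 <- f1; f2$time <- parse_timestamp("2025-03-01-10-15-00")
  tracks <- track_series(list(f1, f2))
  expect_length(tracks, 16)
  expect_true(all(vapply(tracks, function(t) length(t$observations),
                         integer(1)) == 2))

  # one leaf grown concentrically (IoU ~ 0.56 > 0.5): id inherited
  grown <- make_grid_frame()
  big <- rect_mask(dim, 48, 48, 14, 14)   # vs 10x10 at (50, 50)
  expect_gt(mask_iou(instance_raster(grown[[1]]), big), 0.5)
  grown[[1]] <- instance_mask(big)
  f3 <- f2; f3$time <- parse_timestamp("2025-03-01-10-30-00")
  f3$instances <- grown
  tracks <- track_series(list(f1, f2, f3))
  expect_length(tracks, 16)
  expect_equal(tracks[[1]]$observations[[3]]$pixel_count, 196)

  # a displaced mask with max IoU below threshold opens id 16
  moved <- make_grid_frame()
  off <- rect_mask(dim, 58, 50, 10, 10)   # IoU 2/18 vs original
  expect_lt(mask_iou(instance_raster(moved[[1]]), off), 0.5)
  moved[[1]] <- instance_mask(off)
  f4 <- f3; f4$time <- parse_timestamp("2025-03-01-10-45-00")
  f4$instances <- moved
  tracks <- track_series(list(f1, f2, f4))
  ids <- vapply(tracks, `[[`, integer(1), "leaf_id")
  expect_equal(sort(ids), 0:16)
  # observation conservation: every processed instance landed in a track
  expect_equal(sum(vapply(tracks, function(t) length(t$observations),
                          integer(1))), 16 * 3)
})

test_that("greedy conflict resolution gives the contested track to the higher IoU", {
  dim <- c(100, 100)
  prev <- rect_mask(dim, 40, 40, 10, 10)
  f1 <- structure(list(time = parse_timestamp("2025-03-01-00-00-00"),
                       dim = dim,
                       instances = list(instance_mask(prev))),
                  class = "frame_observation")
  tracks <- list(leaftracker:::new_track(0L, f1$time, f1$instances[[1]], 1L))
  # two candidates both above threshold against track 0
  cand_hi <- instance_mask(rect_mask(dim, 40, 40, 10, 11))  # IoU ~0.91
  cand_lo <- instance_mask(rect_mask(dim, 41, 40, 10, 10))  # IoU ~0.82
  f2 <- f1; f2$time <- f1$time + 900
  f2$instances <- list(cand_lo, cand_hi)
  out <- match_frame(tracks, f2, frame_idx = 2L)
  ids <- vapply(out, `[[`, integer(1), "leaf_id")
  winner <- out[[which(ids == 0)]]
  expect_equal(winner$last$pixel_count, cand_hi$pixel_count)
  expect_length(out, 2)  # loser opened a fresh track
})

test_that("tracking recovers all 16 identities on a growing synthetic series", {
  spec <- small_scene_spec()
  scene <- render_scene(spec, seed = 5)
  tracks <- track_series(scene$frames)
  expect_length(tracks, 16)
  df <- tracks_to_df(tracks)
  expect_equal(nrow(df), 16 * length(scene$frames))

  # every track stays on one ground-truth leaf (nearest-centroid mapping)
  gt <- scene$ground_truth
  gt_key <- paste(gt$frame, round(gt$cx), round(gt$cy))
  for (tr in tracks) {
    true_ids <- vapply(seq_along(tr$observations), function(i) {
      o <- tr$observations[[i]]
      d <- (gt$cx - o$centroid[["cx"]])^2 + (gt$cy - o$centroid[["cy"]])^2
      d[gt$frame != tr$frames[i]] <- Inf
      gt$leaf_id[which.min(d)]
    }, numeric(1))
    expect_length(unique(true_ids), 1)
    expect_equal(unique(true_ids), tr$leaf_id)
  }
})
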