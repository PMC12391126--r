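test_that("frame schedules follow the half-open window convention", {
  # 1 h window at 30-min interval: frames at start and start + 30 min only
  s <- schedule_frames(c(0, 1), 30)
  expect_length(s, 2)
  expect_equal(attr(s, "t_h"), c(0, 0.5))

  # the reference monitoring window: 156 h at 15-min intervals = 624 frames
  expect_length(schedule_frames(c(36, 192), 15), 624)

  expect_length(schedule_frames(c(0, 24), 60), 24)
  expect_error(schedule_frames(c(0, 24), 0), "positive")

  # closed form holds across random valid specs
  set.seed(13)
  for (i in 1:20) {
    start <- sample(0:48, 1)
    len <- sample(1:200, 1)
    interval <- sample(c(5, 10, 15, 20, 30, 60), 1)
    got <- length(schedule_frames(c(start, start + len), interval))
    expect_equal(got, ceiling(len * 60 / interval))
  }
})

test_that("logistic growth has the stated asymptote, midpoint and inhibition ordering", {
  # t -> infinity limit is f * A_max
  expect_equal(leaf_area_at(1e6, a_max_mm2 = 900, f = 0.5), 450)
  # at the midpoint the curve reaches half its asymptote
  expect_equal(leaf_area_at(123, a_max_mm2 = 900, midpoint_h = 123), 450)
  # monotone non-decreasing in t
  t <- seq(0, 300, by = 1)
  expect_true(all(diff(leaf_area_at(t)) >= 0))
  # control exceeds stressed throughout the monitoring window (inhibition
  # scales rate as well as asymptote, so the curves can cross well before
  # monitoring starts; within the observed window CK dominates)
  f60 <- inhibition_multiplier(60)
  expect_lt(f60, 1)
  tw <- seq(36, 300, by = 1)
  expect_true(all(leaf_area_at(tw) > leaf_area_at(tw, f = f60)))
  # f(CK) = 1 and f strictly decreasing in concentration
  conc <- seq(0, 60, by = 10)
  fs <- inhibition_multiplier(conc)
  expect_equal(fs[1], 1)
  expect_true(all(diff(fs) < 0))
})

test_that("rendered masks hit the analytic area within rasterization error", {
  # pure ellipse, no jitter: pixel count within 3% of pi*a*b
  spec <- small_scene_spec(jitter_amp = 0)
  scene <- render_scene(spec, seed = 2)
  gt <- scene$ground_truth
  big <- gt$target_px >= 100
  rel <- abs(gt$rendered_px - gt$target_px) / gt$target_px
  expect_lt(max(rel[big]), 0.03)

  # jittered boundary keeps the area oracle valid
  scene2 <- render_scene(small_scene_spec(jitter_amp = 0.03), seed = 2)
  gt2 <- scene2$ground_truth
  rel2 <- abs(gt2$rendered_px - gt2$target_px) / gt2$target_px
  expect_lt(mean(rel2[gt2$target_px >= 100]), 0.03)
})

test_that("scene structure: 16 tracks, determinism, collision guard", {
  spec <- small_scene_spec()
  scene <- render_scene(spec, seed = 7)
  expect_equal(length(unique(scene$ground_truth$leaf_id)), 16)
  expect_length(scene$frames[[1]]$instances, 16)

  # same seed, same scene (including instance order and pixel data)
  scene2 <- render_scene(spec, seed = 7)
  expect_identical(scene$ground_truth, scene2$ground_truth)
  expect_identical(scene$frames[[5]]$instances,
                   scene2$frames[[5]]$instances)

  # an asymptote too large for the pitch is rejected in non-occlusion mode
  expect_error(render_scene(small_scene_spec(a_max_mm2 = 6000), seed = 1),
               "collision")
  # ... but allowed when occlusion is explicitly requested
  expect_no_error(render_scene(
    small_scene_spec(a_max_mm2 = 6000, allow_occlusion = TRUE,
                     window_h = c(36, 60)), seed = 1))
})

test_that("end-to-end merge -> tracking -> phenotype recovers the ground truth", {
  spec <- small_scene_spec()
  scene <- render_scene(spec, seed = 9)
  tracks <- track_series(scene$frames)
  expect_length(tracks, 16)

  df <- tracks_to_df(tracks)
  areas <- area_series(df, spec$calibration)
  gt <- scene$ground_truth

  # per-leaf areas within 3% of the analytic ground truth
  key <- paste(areas$leaf_id, round(areas$t_h, 6))
  gkey <- paste(gt$leaf_id, round(gt$t_h - gt$t_h[1], 6))
  matched <- match(key, gkey)
  expect_false(anyNA(matched))
  rel <- abs(areas$area_mm2 - gt$area_mm2[matched]) / gt$area_mm2[matched]
  expect_lt(mean(rel[gt$target_px[matched] >= 100]), 0.03)

  # mean growth-rate ordering across concentrations matches f(c)
  conc <- c(0, 30, 60)
  mean_rates <- vapply(conc, function(cc) {
    sc <- render_scene(small_scene_spec(concentration_mmol = cc), seed = 9)
    a <- area_series(tracks_to_df(track_series(sc$frames)),
                     sc$spec$calibration)
    mean(growth_rate(a)$rate_mm2_per_h)
  }, numeric(1))
  expect_true(all(diff(mean_rates) < 0))
})

test_that("written scenes carry timestamped frames, polygon TXT and area CSV", {
  dir <- withr::local_tempdir()
  spec <- small_scene_spec(window_h = c(36, 42), frame_interval_min = 120)
  scene <- render_scene(spec, seed = 3)
  write_scene(scene, dir)
  pngs <- list.files(dir, pattern = "\\.png$")
  txts <- list.files(dir, pattern = "\\.txt$")
  expect_length(pngs, 3)
  expect_length(txts, 3)
  expect_match(pngs, "^\\d{4}(-\\d{2}){5}\\.png$")

  # polygon ground truth rasterizes close to the rendered instances
  fr <- scene$frames[[1]]
  tok <- format_timestamp(fr$time)
  recs <- read_polygon_txt(file.path(dir, paste0(tok, ".txt")))
  expect_length(recs, 16)
  obs <- load_instances(recs, c(spec$width_px, spec$height_px))
  merged_poly <- merge_masks(lapply(obs$instances, instance_raster))
  merged_inst <- merge_masks(lapply(fr$instances, instance_raster))
  expect_gt(mask_iou(merged_poly, merged_inst), 0.95)

  csv <- utils::read.csv(file.path(dir, "ground_truth_areas.csv"))
  expect_equal(nrow(csv), 3 * 16)
})
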