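#' Synthetic growing-leaf scene description
#'
#' Describes an incubator-style experiment the generator can render: a
#' `rows x cols` grid of leaves (default 4 x 4, the planting layout of one
#' culture box), imaged on a fixed schedule over a monitoring window, each
#' leaf following a logistic expansion curve optionally damped by a
#' concentration-dependent inhibition multiplier (salt stress). Leaves are
#' rendered as analytic closed curves (jittered ellipses) so the true area
#' is known exactly at every frame.
#'
#' Defaults emulate the reference experiment: 15-minute frames over the
#' 36 h - 192 h window (156 h of monitoring), 250 mm scene width, logistic
#' asymptote 1200 mm^2 per leaf with midpoint near 123 h — slow early
#' growth with the steepest expansion in the middle/late seedling stage,
#' reaching box-mean areas of a few hundred mm^2 by day 2-3.
#'
#' @param rows,cols planting grid (default 4 x 4).
#' @param pitch_px inter-leaf spacing in pixels (default 450, i.e. 1800 px
#'   across four columns).
#' @param margin_px border margin (default `pitch_px / 2`).
#' @param frame_interval_min capture interval in minutes (default 15).
#' @param window_h monitoring window `c(start_h, end_h)` in hours since
#'   sowing (default `c(36, 192)`).
#' @param a_max_mm2 logistic asymptote per leaf, mm^2.
#' @param growth_rate_per_h logistic rate constant, 1/h.
#' @param midpoint_h logistic midpoint, hours.
#' @param concentration_mmol NaCl-style stressor concentration; 0 = control.
#' @param inhibition_scale e-folding scale of the inhibition multiplier
#'   `f(c) = exp(-c / inhibition_scale)`.
#' @param aspect ellipse minor/major axis ratio in `(0, 1]`.
#' @param jitter_amp boundary jitter amplitude (fraction of radius).
#' @param jitter_harmonics number of Fourier harmonics in the jitter.
#' @param leaf_var relative spread of per-leaf asymptotes (uniform
#'   `+/- leaf_var`).
#' @param midpoint_jitter_h per-leaf midpoint jitter, hours.
#' @param allow_occlusion permit neighbouring leaves to overlap in late
#'   frames instead of rejecting the spec.
#' @param physical_width_mm physical width of the imaged scene, mm.
#' @param origin calendar time of sowing (`t = 0`), "YYYY-MM-DD-HH-MM-SS".
#' @return a `scene_spec` list; image dimensions and the derived
#'   [calibration()] are attached as `width_px`, `height_px`, `calibration`.
#' @export
scene_spec <- function(rows = 4L, cols = 4L, pitch_px = 450,
                       margin_px = NULL, frame_interval_min = 15,
                       window_h = c(36, 192), a_max_mm2 = 1200,
                       growth_rate_per_h = 0.021, midpoint_h = 123,
                       concentration_mmol = 0, inhibition_scale = 60,
                       aspect = 0.8, jitter_amp = 0.03,
                       jitter_harmonics = 3L, leaf_var = 0.1,
                       midpoint_jitter_h = 6, allow_occlusion = FALSE,
                       physical_width_mm = 250,
                       origin = "2025-03-01-00-00-00") {
  stopifnot(rows >= 1, cols >= 1, pitch_px > 0, frame_interval_min > 0,
            length(window_h) == 2, window_h[1] < window_h[2],
            a_max_mm2 > 0, growth_rate_per_h > 0, aspect > 0, aspect <= 1,
            jitter_amp >= 0, concentration_mmol >= 0, inhibition_scale > 0)
  if (is.null(margin_px)) margin_px <- pitch_px / 2
  width_px <- as.integer(round(2 * margin_px + (cols - 1) * pitch_px))
  height_px <- as.integer(round(2 * margin_px + (rows - 1) * pitch_px))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_px = pitch_px, margin_px = margin_px,
                 frame_interval_min = frame_interval_min,
                 window_h = window_h, a_max_mm2 = a_max_mm2,
                 growth_rate_per_h = growth_rate_per_h,
                 midpoint_h = midpoint_h,
                 concentration_mmol = concentration_mmol,
                 inhibition_scale = inhibition_scale, aspect = aspect,
                 jitter_amp = jitter_amp,
                 jitter_harmonics = as.integer(jitter_harmonics),
                 leaf_var = leaf_var, midpoint_jitter_h = midpoint_jitter_h,
                 allow_occlusion = allow_occlusion,
                 width_px = width_px, height_px = height_px,
                 calibration = calibration(width_px, physical_width_mm),
                 origin = parse_timestamp(origin)),
            class = "scene_spec")
}

#' Concentration-dependent growth inhibition multiplier
#'
#' `f(c) = exp(-c / scale)`: 1 at the control condition (c = 0) and
#' strictly decreasing in concentration. Scales both the logistic
#' asymptote and the rate constant in [leaf_area_at()].
#'
#' @param concentration_mmol stressor concentration (>= 0).
#' @param scale e-folding scale (same units).
#' @return multiplier in `(0, 1]`.
#' @export
inhibition_multiplier <- function(concentration_mmol, scale = 60) {
  stopifnot(all(concentration_mmol >= 0), scale > 0)
  exp(-concentration_mmol / scale)
}

#' Analytic leaf area at a given time
#'
#' Logistic expansion damped by the inhibition multiplier `f`:
#' `A(t) = f * A_max / (1 + exp(-rate * f * (t - midpoint)))`. Monotone
#' non-decreasing in `t`, with asymptote `f * A_max` and half the asymptote
#' reached at the midpoint.
#'
#' @param t_h time(s) in hours (>= 0).
#' @param a_max_mm2 asymptotic area, mm^2.
#' @param rate_per_h logistic rate constant, 1/h.
#' @param midpoint_h logistic midpoint, hours.
#' @param f inhibition multiplier in `(0, 1]` (see
#'   [inhibition_multiplier()]).
#' @return area(s) in mm^2.
#' @export
leaf_area_at <- function(t_h, a_max_mm2 = 1200, rate_per_h = 0.021,
                         midpoint_h = 123, f = 1) {
  stopifnot(all(t_h >= 0), f > 0, f <= 1)
  f * a_max_mm2 / (1 + exp(-rate_per_h * f * (t_h - midpoint_h)))
}

#' Frame capture schedule over a half-open monitoring window
#'
#' Timestamps at `start_h`, `start_h + interval`, ... strictly before
#' `end_h` (half-open convention), anchored at the calendar origin. A
#' 156-hour window at 15-minute intervals yields 624 frames.
#'
#' @param window_h `c(start_h, end_h)` in hours.
#' @param interval_min capture interval in minutes (> 0).
#' @param origin `POSIXct` calendar time of `t = 0`.
#' @return `POSIXct` vector of frame times, with attribute `"t_h"` (hours).
#' @export
schedule_frames <- function(window_h = c(36, 192), interval_min = 15,
                            origin = parse_timestamp("2025-03-01-00-00-00")) {
  if (interval_min <= 0) stop("frame interval must be positive")
  stopifnot(length(window_h) == 2, window_h[1] < window_h[2])
  span_min <- (window_h[2] - window_h[1]) * 60
  n <- ceiling(span_min / interval_min)
  t_h <- window_h[1] + (seq_len(n) - 1) * interval_min / 60
  out <- origin + t_h * 3600
  attr(out, "t_h") <- t_h
  out
}

## One leaf's rendered crop: jittered-ellipse membership on a local pixel
## window. Returns NULL when no pixel centre falls inside.
render_leaf_crop <- function(cx, cy, target_px, aspect, orient, jc, js,
                             width, height) {
  mean_m2 <- 1 + sum(jc^2 + js^2) / 2
  ab <- target_px / (pi * mean_m2)
  if (ab <= 0) return(NULL)
  a <- sqrt(ab / aspect)
  b <- aspect * a
  rmax <- a * (1 + sum(abs(jc)) + sum(abs(js)))
  x0 <- max(0L, floor(cx - rmax - 1)); x1 <- min(width - 1L, ceiling(cx + rmax + 1))
  y0 <- max(0L, floor(cy - rmax - 1)); y1 <- min(height - 1L, ceiling(cy + rmax + 1))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  px <- outer(rep(1, length(ys)), xs + 0.5) - cx
  py <- outer(ys + 0.5, rep(1, length(xs))) - cy
  u <- px * cos(-orient) - py * sin(-orient)
  v <- px * sin(-orient) + py * cos(-orient)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  theta <- atan2(v / b, u / a)
  m <- 1
  for (k in seq_along(jc)) {
    m <- m + jc[k] * cos(k * theta) + js[k] * sin(k * theta)
  }
  inside <- rho <= m
  if (!any(inside)) return(NULL)
  list(crop = inside, x0 = x0, y0 = y0,
       shape = list(a = a, b = b, orient = orient, jc = jc, js = js,
                    cx = cx, cy = cy))
}

instance_from_crop <- function(crop, x0, y0, dim_hw) {
  rows <- which(rowSums(crop) > 0); cols <- which(colSums(crop) > 0)
  crop <- crop[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)],
               drop = FALSE]
  y0 <- y0 + rows[1] - 1L; x0 <- x0 + cols[1] - 1L
  fg <- which(crop, arr.ind = TRUE)
  structure(list(dim = dim_hw,
                 bbox = c(x_min = x0, y_min = y0,
                          x_max = x0 + ncol(crop) - 1L,
                          y_max = y0 + nrow(crop) - 1L),
                 centroid = c(cx = x0 + mean(fg[, 2]) - 1,
                              cy = y0 + mean(fg[, 1]) - 1),
                 pixel_count = nrow(fg),
                 crop = crop),
            class = "instance_mask")
}

#' Render a synthetic leaf-growth scene with analytic ground truth
#'
#' For every scheduled frame, each leaf is drawn as a smooth closed curve
#' (an ellipse with bounded, area-corrected Fourier boundary jitter) whose
#' interior pixel count targets the analytic area of [leaf_area_at()]
#' divided by the pixel area. Per-leaf biology (asymptote, rate, midpoint,
#' orientation, jitter shape) is drawn once from the seeded generator;
#' identical seeds give identical scenes. Instance order within each frame
#' is shuffled so downstream tracking cannot rely on input order.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed for all randomness.
#' @param shuffle_instances randomise per-frame instance order (default
#'   TRUE).
#' @return a `leaf_scene`: `spec`, `frames` (list of `frame_observation`),
#'   `ground_truth` (data frame: `frame`, `time`, `t_h`, `leaf_id`,
#'   `area_mm2` analytic, `target_px`, `rendered_px`, `cx`, `cy`), and
#'   `leaves` (per-leaf drawn parameters).
#' @export
render_scene <- function(spec = scene_spec(), seed = 1L,
                         shuffle_instances = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  f <- inhibition_multiplier(spec$concentration_mmol, spec$inhibition_scale)
  px_area <- pixel_area(spec$calibration)
  n_leaf <- spec$rows * spec$cols
  times <- schedule_frames(spec$window_h, spec$frame_interval_min,
                           spec$origin)
  t_h <- attr(times, "t_h")
  state <- withr::with_seed(seed, {
    leaves <- lapply(seq_len(n_leaf) - 1L, function(id) {
      row <- id %/% spec$cols; col <- id %% spec$cols
      nh <- spec$jitter_harmonics
      list(leaf_id = id,
           cx = spec$margin_px + col * spec$pitch_px + stats::runif(1, -3, 3),
           cy = spec$margin_px + row * spec$pitch_px + stats::runif(1, -3, 3),
           a_max = spec$a_max_mm2 *
             stats::runif(1, 1 - spec$leaf_var, 1 + spec$leaf_var),
           rate = spec$growth_rate_per_h * stats::runif(1, 0.9, 1.1),
           midpoint = spec$midpoint_h +
             stats::runif(1, -spec$midpoint_jitter_h, spec$midpoint_jitter_h),
           orient = stats::runif(1, 0, 2 * pi),
           jc = stats::runif(nh, -1, 1) * spec$jitter_amp / nh,
           js = stats::runif(nh, -1, 1) * spec$jitter_amp / nh)
    })
    orders <- lapply(seq_along(times), function(i) {
      if (shuffle_instances) sample.int(n_leaf) else seq_len(n_leaf)
    })
    list(leaves = leaves, orders = orders)
  })
  leaves <- state$leaves
  if (!spec$allow_occlusion) {
    max_r <- vapply(leaves, function(lf) {
      amp <- sum(abs(lf$jc)) + sum(abs(lf$js))
      t_px <- lf$a_max * f / px_area   # asymptotic pixel area
      sqrt(t_px / (pi * spec$aspect)) * (1 + amp)
    }, numeric(1))
    if (any(max_r > spec$pitch_px / 2 - 1) ||
        any(max_r > spec$margin_px)) {
      stop("leaf asymptote too large for the grid pitch: guaranteed ",
           "collision; reduce a_max_mm2 or enlarge pitch_px ",
           "(or set allow_occlusion = TRUE)")
    }
  }
  dim_hw <- c(spec$height_px, spec$width_px)
  frames <- vector("list", length(times))
  gt <- vector("list", length(times))
  for (i in seq_along(times)) {
    insts <- list(); rows <- list()
    for (lf in leaves) {
      area <- leaf_area_at(t_h[i], lf$a_max, lf$rate, lf$midpoint, f)
      target_px <- area / px_area
      rc <- render_leaf_crop(lf$cx, lf$cy, target_px, spec$aspect,
                             lf$orient, lf$jc, lf$js,
                             spec$width_px, spec$height_px)
      inst <- if (is.null(rc)) NULL else
        instance_from_crop(rc$crop, rc$x0, rc$y0, dim_hw)
      rows <- c(rows, list(data.frame(
        frame = i, time = times[i], t_h = t_h[i], leaf_id = lf$leaf_id,
        area_mm2 = area, target_px = target_px,
        rendered_px = if (is.null(inst)) 0L else inst$pixel_count,
        cx = lf$cx, cy = lf$cy)))
      if (!is.null(inst)) insts <- c(insts, list(inst))
    }
    ord <- state$orders[[i]]
    frames[[i]] <- structure(
      list(time = times[i], dim = dim_hw,
           instances = insts[ord[ord <= length(insts)]]),
      class = "frame_observation")
    gt[[i]] <- do.call(rbind, rows)
  }
  structure(list(spec = spec, seed = seed, frames = frames,
                 ground_truth = do.call(rbind, gt), leaves = leaves),
            class = "leaf_scene")
}

#' @export
print.leaf_scene <- function(x, ...) {
  cat(sprintf("leaf_scene: %d frames, %d leaves, %dx%d px, c = %g mmol/L\n",
              length(x$frames), length(x$leaves), x$spec$width_px,
              x$spec$height_px, x$spec$concentration_mmol))
  invisible(x)
}

## Boundary polygon of one rendered leaf at one frame (pixel coordinates).
leaf_boundary_polygon <- function(shape, n = 72) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  m <- 1
  for (k in seq_along(shape$jc)) {
    m <- m + shape$jc[k] * cos(k * theta) + shape$js[k] * sin(k * theta)
  }
  u <- shape$a * m * cos(theta); v <- shape$b * m * sin(theta)
  cbind(shape$cx + u * cos(shape$orient) - v * sin(shape$orient),
        shape$cy + u * sin(shape$orient) + v * cos(shape$orient))
}

#' Write a rendered scene to disk (frames, annotations, areas)
#'
#' Emits, per frame, a raster image named with the "YYYY-MM-DD-HH-MM-SS"
#' token (soil-textured background, green leaves) and a matching
#' ground-truth polygon TXT in the normalized segmentation dialect, plus a
#' CSV of analytic areas for the whole scene.
#'
#' @param scene a `leaf_scene` from [render_scene()].
#' @param dir output directory (created if needed).
#' @param format image format, `"png"` (default) or `"jpg"`.
#' @param image_seed seed for the background texture.
#' @return the output directory, invisibly.
#' @export
write_scene <- function(scene, dir, format = c("png", "jpg"),
                        image_seed = scene$seed + 1L) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- scene$spec
  w <- spec$width_px; h <- spec$height_px
  px_area <- pixel_area(spec$calibration)
  f <- inhibition_multiplier(spec$concentration_mmol, spec$inhibition_scale)
  for (i in seq_along(scene$frames)) {
    fr <- scene$frames[[i]]
    tok <- format_timestamp(fr$time)
    img <- withr::with_seed(image_seed + i, {
      base <- array(0, dim = c(w, h, 3))
      noise <- matrix(stats::rnorm(w * h, 0, 0.02), w, h)
      base[, , 1] <- 0.35 + noise; base[, , 2] <- 0.25 + noise
      base[, , 3] <- 0.15 + noise
      base
    })
    merged <- merge_masks(lapply(fr$instances, instance_raster))
    fg <- t(merged) > 0   # [x, y]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fg] <- c(0.20, 0.55, 0.22)[ch]
      img[, , ch] <- plane
    }
    EBImage::writeImage(EBImage::Image(pmin(pmax(img, 0), 1),
                                       colormode = "Color"),
                        file.path(dir, paste0(tok, ".", format)))
    th <- interval_hours(spec$origin, fr$time)
    polys <- lapply(scene$leaves, function(lf) {
      area <- leaf_area_at(th, lf$a_max, lf$rate, lf$midpoint, f)
      target_px <- area / px_area
      rc <- render_leaf_crop(lf$cx, lf$cy, target_px, spec$aspect,
                             lf$orient, lf$jc, lf$js, w, h)
      if (is.null(rc)) NULL else leaf_boundary_polygon(rc$shape)
    })
    polys <- Filter(Negate(is.null), polys)
    write_polygon_txt(polygons_to_txt_lines(polys, w, h),
                      file.path(dir, paste0(tok, ".txt")))
  }
  gt <- scene$ground_truth
  gt$time <- format_timestamp(gt$time)
  for (cc in c("t_h", "area_mm2", "target_px", "cx", "cy")) {
    gt[[cc]] <- sprintf("%.6f", gt[[cc]])
  }
  utils::write.csv(gt, file.path(dir, "ground_truth_areas.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
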