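# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately uses a different algorithm from the package code
# it checks.

# Ray-casting point-in-polygon test (per-point loop; the package uses a
# scan-line fill).
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterize by testing every pixel centre independently.
rasterize_oracle <- function(vertices, width, height) {
  m <- matrix(0L, height, width)
  for (y in seq_len(height) - 1L) {
    for (x in seq_len(width) - 1L) {
      if (point_in_polygon(x + 0.5, y + 0.5, vertices)) m[y + 1, x + 1] <- 255L
    }
  }
  m
}

# Brute-force all-point-interpolated AP: for every achieved recall step,
# scan the whole detection list for the maximum precision at recall >= r
# (no cumulative-maximum trick).
ap_oracle <- function(tp_flags, n_gt) {
  k <- seq_along(tp_flags)
  rec <- cumsum(tp_flags) / n_gt
  prec <- cumsum(tp_flags) / k
  ap <- 0
  prev_r <- 0
  for (i in k) {
    if (rec[i] > prev_r) {
      p_int <- max(prec[rec >= rec[i]])
      ap <- ap + (rec[i] - prev_r) * p_int
      prev_r <- rec[i]
    }
  }
  ap
}

# Solid axis-aligned rectangle mask; corner (x0, y0), size wpx x hpx,
# inside a frame of `dim` = c(height, width).
rect_mask <- function(dim, x0, y0, wpx, hpx) {
  m <- matrix(0L, dim[1], dim[2])
  m[(y0 + 1):(y0 + hpx), (x0 + 1):(x0 + wpx)] <- 255L
  m
}

# Small fast scene used by several tests: 4x4 grid at 80 px pitch
# (320 x 320 frame), calibrated to the standard 250 mm scene width.
small_scene_spec <- function(window_h = c(36, 180),
                             frame_interval_min = 120, ...) {
  scene_spec(pitch_px = 80, frame_interval_min = frame_interval_min,
             window_h = window_h, ...)
}
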