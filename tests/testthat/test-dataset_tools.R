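test_that("retention filter removes leading/trailing windows and flagged frames once", {
  t0 <- parse_timestamp("2025-03-01-00-00-00")
  frames <- paste0(format_timestamp(t0 + (0:9) * 3600), ".jpg")

  # no exclusions: input unchanged (already time-ordered)
  expect_equal(as.vector(filter_frames(frames)), frames)

  # 3 leading (one also flagged) + 1 other flagged -> 6 retained
  kept <- filter_frames(frames, exclude_before = 3, quality_flags = c(3, 5))
  expect_length(kept, 6)
  expect_equal(as.vector(kept), frames[c(4, 6, 7, 8, 9, 10)])
  counts <- attr(kept, "excluded")
  expect_equal(unname(counts["total"]), 4)

  # survivors come back in time order even if input is shuffled
  set.seed(1)
  shuf <- sample(frames)
  expect_equal(as.vector(filter_frames(shuf)),
               shuf[order(parse_timestamp(shuf))])

  # windows covering everything: empty result with a warning, not an error
  expect_warning(out <- filter_frames(frames, exclude_before = 100),
                 "every frame")
  expect_length(out, 0)

  expect_error(filter_frames(frames, quality_flags = 99), "index")
})

test_that("retention arithmetic: output size is N minus the exclusion-set union", {
  t0 <- parse_timestamp("2025-03-01-00-00-00")
  set.seed(21)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    frames <- t0 + (seq_len(n) - 1) * 1800
    before <- sample(0:10, 1) * 0.5
    after <- sample(0:10, 1) * 0.5
    flags <- sample(seq_len(n), sample(0:20, 1))
    kept <- filter_frames(frames, before, after, flags)
    lead <- which(interval_hours(frames[1], frames) < before)
    trail <- which(interval_hours(frames, frames[n]) < after)
    expect_length(kept, n - length(union(union(lead, trail), flags)))
  }
})

test_that("70:20:10 split uses nearest-integer train/val sizes with remainder to test", {
  sizes <- lengths(split_dataset(seq_len(2707), seed = 4))
  expect_equal(unname(sizes), c(1895, 541, 271))

  sizes10 <- lengths(split_dataset(seq_len(10), seed = 4))
  expect_equal(unname(sizes10), c(7, 2, 1))

  expect_error(split_dataset(1:10, c(train = 0.7, val = 0.2, test = 0.2)),
               "sum to 1")
  expect_error(split_ratios(0.5, 0.2, 0.2), "sum to 1")
})

test_that("splits are seed-deterministic partitions", {
  items <- sprintf("img_%03d.jpg", 1:97)
  a <- split_dataset(items, seed = 12)
  b <- split_dataset(items, seed = 12)
  expect_identical(a, b)
  c2 <- split_dataset(items, seed = 13)
  expect_false(identical(a, c2))
  # disjoint subsets whose union is the input
  expect_setequal(c(a$train, a$val, a$test), items)
  expect_length(intersect(a$train, a$val), 0)
  expect_length(intersect(a$train, a$test), 0)
  expect_length(intersect(a$val, a$test), 0)
  # sizes always sum to N
  set.seed(30)
  for (n in sample(3:500, 10)) {
    expect_equal(sum(lengths(split_dataset(seq_len(n), seed = n))), n)
  }
})

test_that("identity augmentation is a no-op on image and polygons", {
  set.seed(8)
  img <- array(stats::runif(40 * 30 * 3), dim = c(40, 30, 3))
  poly <- matrix(c(5, 5, 20, 5, 20, 20, 5, 20), ncol = 2, byrow = TRUE)
  ident <- augment_spec(rotation_deg = c(0, 0), hue_deg = c(0, 0),
                        brightness = c(0, 0), blur_px = 0, noise_frac = 0)
  out <- augment(img, list(poly), spec = ident, seed = 3)
  expect_equal(out$image, img)
  expect_equal(out$polygons[[1]], poly)
})

test_that("polygon rotation matches a closed-form complex-number oracle", {
  w <- 100; h <- 80
  poly <- matrix(c(30, 20, 70, 25, 60, 60, 25, 55), ncol = 2, byrow = TRUE)
  spec30 <- augment_spec(rotation_deg = c(30, 30), hue_deg = c(0, 0),
                         brightness = c(0, 0), blur_px = 0, noise_frac = 0)
  img <- array(0.5, dim = c(w, h, 3))
  out <- augment(img, list(poly), spec = spec30, seed = 1)
  # oracle: rotate about the image centre using complex arithmetic
  z <- complex(real = poly[, 1] - w / 2, imaginary = poly[, 2] - h / 2)
  zr <- z * exp(1i * 30 * pi / 180)
  expect_equal(out$polygons[[1]][, 1], Re(zr) + w / 2, tolerance = 0.5)
  expect_equal(out$polygons[[1]][, 2], Im(zr) + h / 2, tolerance = 0.5)

  # 90-degree rotation of a centred square: same vertex set up to order
  sq <- matrix(c(40, 30, 60, 30, 60, 50, 40, 50), ncol = 2, byrow = TRUE)
  spec90 <- augment_spec(rotation_deg = c(90, 90), hue_deg = c(0, 0),
                         brightness = c(0, 0), blur_px = 0, noise_frac = 0)
  out90 <- augment(img, list(sq), spec = spec90, seed = 1)
  got <- round(out90$polygons[[1]], 6)
  expect_setequal(unname(split(got, seq_len(4))),
                  unname(split(sq, seq_len(4))))
})

test_that("rotation transforms image and polygons consistently", {
  # a rectangle drawn into the image should still be traced by its rotated
  # polygon after augmentation
  w <- h <- 101
  img <- array(0, dim = c(w, h))
  img[31:70, 41:60] <- 1   # x 30..69, y 40..59 (0-based)
  poly <- matrix(c(30, 40, 70, 40, 70, 60, 30, 60), ncol = 2, byrow = TRUE)
  spec <- augment_spec(rotation_deg = c(25, 25), hue_deg = c(0, 0),
                       brightness = c(0, 0), blur_px = 0, noise_frac = 0)
  out <- augment(img, list(poly), spec = spec, seed = 2)
  img_mask <- matrix(0L, h, w)
  img_mask[t(out$image) > 0.5] <- 255L
  poly_mask <- rasterize_polygon(out$polygons[[1]], w, h)
  expect_gt(mask_iou(img_mask, poly_mask), 0.9)
})

test_that("geometric augmentation approximately preserves polygon area", {
  area_shoelace <- function(p) {
    n <- nrow(p)
    j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  set.seed(17)
  poly <- matrix(c(30, 20, 70, 25, 60, 60, 25, 55), ncol = 2, byrow = TRUE)
  img <- array(0.5, dim = c(120, 120))
  for (i in 1:5) {
    spec <- augment_spec(hue_deg = c(0, 0), brightness = c(0, 0),
                         blur_px = 0, noise_frac = 0)
    out <- augment(img, list(poly), spec = spec, seed = i)
    expect_equal(nrow(out$polygons[[1]]), nrow(poly))
    expect_lt(abs(area_shoelace(out$polygons[[1]]) - area_shoelace(poly)) /
                area_shoelace(poly), 0.01)
  }
})

test_that("photometric parameters stay inside the spec ranges and are seeded", {
  img <- array(stats::runif(30 * 30 * 3), dim = c(30, 30, 3))
  spec <- augment_spec()
  p1 <- augment(img, spec = spec, seed = 42)$params
  p2 <- augment(img, spec = spec, seed = 42)$params
  expect_identical(p1, p2)
  expect_true(p1$rotation >= -45 && p1$rotation <= 45)
  expect_true(p1$hue >= -180 && p1$hue <= 180)
  expect_true(p1$brightness >= -0.9 && p1$brightness <= 0.9)
  expect_true(p1$blur >= 0 && p1$blur <= 5.7)
  expect_true(p1$noise >= 0 && p1$noise <= 0.0826)
})
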