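#' Retention filter for a timestamped frame list
#'
#' Removes (i) frames inside the leading exclusion window (within
#' `exclude_before` hours of the first frame, half-open), (ii) frames
#' inside the trailing window (within `exclude_after` hours of the last
#' frame, half-open), and (iii) an explicitly flagged subset (quality
#' problems: environmental changes, exposure anomalies, blur). Exclusions
#' are combined with set semantics — a frame removed once even if it falls
#' in several categories. Survivors are returned in time order.
#'
#' @param frames character filenames carrying timestamp tokens, or a
#'   `POSIXct` vector.
#' @param exclude_before,exclude_after window lengths in hours (>= 0).
#' @param quality_flags indices (1-based, into `frames`) of flagged frames.
#' @return the retained subset of `frames`, time-ordered, with attribute
#'   `"excluded"` giving the per-category and total exclusion counts.
#' @export
filter_frames <- function(frames, exclude_before = 0, exclude_after = 0,
                          quality_flags = integer(0)) {
  stopifnot(exclude_before >= 0, exclude_after >= 0)
  times <- if (is.character(frames)) parse_timestamp(frames) else frames
  n <- length(frames)
  if (!all(quality_flags %in% seq_len(n))) {
    stop("quality_flags must index into frames")
  }
  lead <- interval_hours(min(times), times) < exclude_before
  trail <- interval_hours(times, max(times)) < exclude_after
  flagged <- seq_len(n) %in% quality_flags
  drop <- lead | trail | flagged
  if (all(drop)) warning("exclusion windows cover every frame")
  kept <- frames[!drop][order(times[!drop])]
  attr(kept, "excluded") <- c(leading = sum(lead), trailing = sum(trail),
                              flagged = sum(flagged), total = sum(drop))
  kept
}

#' Subset ratios for dataset splitting
#'
#' @param train,val,test non-negative proportions summing to 1 (default
#'   70:20:10).
#' @return a named numeric vector.
#' @export
split_ratios <- function(train = 0.7, val = 0.2, test = 0.1) {
  r <- c(train = train, val = val, test = test)
  if (any(r < 0) || abs(sum(r) - 1) > 1e-9) {
    stop("split ratios must be non-negative and sum to 1")
  }
  r
}

#' Seeded train/validation/test split
#'
#' Items are shuffled with the seed, then partitioned. Subset sizes use
#' nearest-integer rounding for train and validation with the remainder
#' going to test (so sizes always sum to the input size); e.g. 2707 items
#' at 70:20:10 give 1895 / 541 / 271.
#'
#' @param items vector or list to split.
#' @param ratios from [split_ratios()].
#' @param seed integer RNG seed (the global RNG state is left untouched).
#' @return list of `train`, `val`, `test` subsets (disjoint, union = input).
#' @export
split_dataset <- function(items, ratios = split_ratios(), seed = 1L) {
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("split ratios must be non-negative and sum to 1")
  }
  n <- length(items)
  stopifnot(n >= 3)
  n_train <- round(n * ratios[["train"]])
  n_val <- round(n * ratios[["val"]])
  n_test <- n - n_train - n_val
  if (n_test < 0) stop("rounding produced a negative test subset")
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = items[perm[seq_len(n_train)]],
       val = items[perm[n_train + seq_len(n_val)]],
       test = items[perm[n_train + n_val + seq_len(n_test)]])
}

#' Augmentation parameter ranges
#'
#' Each transform's parameter is drawn uniformly from its range when the
#' augmentation runs. Defaults are the full ranges used for the reference
#' dataset: rotation +/-45 deg, hue shift +/-180 deg, brightness +/-90%,
#' blur radius up to 5.7 px, salt-and-pepper noise on up to 8.26% of
#' pixels.
#'
#' @param rotation_deg length-2 range, degrees.
#' @param hue_deg length-2 range, degrees.
#' @param brightness length-2 range, fraction (-0.9 = darken 90%).
#' @param blur_px max blur radius, px (Gaussian sigma = radius / 2).
#' @param noise_frac max fraction of pixels replaced by salt/pepper.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(rotation_deg = c(-45, 45), hue_deg = c(-180, 180),
                         brightness = c(-0.9, 0.9), blur_px = 5.7,
                         noise_frac = 0.0826) {
  stopifnot(length(rotation_deg) == 2, length(hue_deg) == 2,
            length(brightness) == 2, blur_px >= 0,
            noise_frac >= 0, noise_frac <= 1)
  structure(list(rotation_deg = sort(rotation_deg), hue_deg = sort(hue_deg),
                 brightness = sort(brightness), blur_px = blur_px,
                 noise_frac = noise_frac),
            class = "augment_spec")
}

## Vectorised HSV -> RGB (h in [0, 360), s, v in [0, 1]); inverse of
## grDevices::rgb2hsv for whole-image arrays.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  pick <- function(c0, c1, c2, c3, c4, c5) {
    out <- c0
    out[i == 1] <- c1[i == 1]; out[i == 2] <- c2[i == 2]
    out[i == 3] <- c3[i == 3]; out[i == 4] <- c4[i == 4]
    out[i == 5] <- c5[i == 5]
    out
  }
  list(r = pick(v, q, p, p, t, v),
       g = pick(t, v, v, q, p, p),
       b = pick(p, p, t, v, v, q))
}

rotate_points <- function(pts, angle_deg, cx, cy) {
  th <- angle_deg * pi / 180
  dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
  cbind(cx + dx * cos(th) - dy * sin(th),
        cy + dx * sin(th) + dy * cos(th))
}

#' Seeded augmentation of an image and its polygon annotations
#'
#' Geometric transforms (rotation about the image centre) are applied
#' identically to the image and to the polygon vertex coordinates;
#' photometric transforms (hue, brightness, blur, salt-and-pepper noise)
#' touch the image only. Parameters are drawn uniformly within the spec
#' ranges from a generator seeded with `seed`. Polygons rotated fully out
#' of the frame are dropped with a warning; partially-out vertices are
#' clipped when the annotation is later serialised.
#'
#' @param image numeric array `[width, height]` (grayscale) or
#'   `[width, height, 3]` (RGB) with values in `[0, 1]` (EBImage layout),
#'   or an `EBImage::Image`.
#' @param polygons list of n x 2 pixel-coordinate polygon matrices.
#' @param spec an [augment_spec()].
#' @param seed integer seed.
#' @return list: `image` (same layout as input), `polygons` (transformed),
#'   `params` (the drawn parameter values).
#' @export
augment <- function(image, polygons = list(), spec = augment_spec(),
                    seed = 1L) {
  img <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  w <- dim(img)[1]; h <- dim(img)[2]
  params <- withr::with_seed(seed, list(
    rotation = stats::runif(1, spec$rotation_deg[1], spec$rotation_deg[2]),
    hue = stats::runif(1, spec$hue_deg[1], spec$hue_deg[2]),
    brightness = stats::runif(1, spec$brightness[1], spec$brightness[2]),
    blur = stats::runif(1, 0, spec$blur_px),
    noise = stats::runif(1, 0, spec$noise_frac),
    noise_seed = sample.int(.Machine$integer.max, 1)
  ))
  out <- EBImage::Image(img,
                        colormode = if (length(dim(img)) == 3) "Color"
                                    else "Grayscale")
  if (params$rotation != 0) {
    out <- EBImage::rotate(out, params$rotation, output.dim = c(w, h),
                           bg.col = "black")
  }
  dat <- EBImage::imageData(out)
  if (params$hue != 0 && length(dim(dat)) == 3) {
    hsv <- grDevices::rgb2hsv(rbind(as.vector(dat[, , 1]),
                                    as.vector(dat[, , 2]),
                                    as.vector(dat[, , 3])),
                              maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1, ] * 360 + params$hue, hsv[2, ], hsv[3, ])
    dat[, , 1] <- rgb$r; dat[, , 2] <- rgb$g; dat[, , 3] <- rgb$b
  }
  if (params$brightness != 0) {
    dat <- pmin(pmax(dat * (1 + params$brightness), 0), 1)
  }
  out <- EBImage::Image(dat, colormode = EBImage::colorMode(out))
  if (params$blur > 0.3) { # gblur needs a non-trivial sigma
    out <- EBImage::gblur(out, sigma = params$blur / 2)
  }
  dat <- EBImage::imageData(out)
  if (params$noise > 0) {
    npx <- w * h
    dat <- withr::with_seed(params$noise_seed, {
      hit <- sample.int(npx, size = round(params$noise * npx))
      val <- stats::rbinom(length(hit), 1, 0.5)
      if (length(dim(dat)) == 3) {
        for (ch in 1:3) {
          plane <- dat[, , ch]; plane[hit] <- val; dat[, , ch] <- plane
        }
      } else {
        dat[hit] <- val
      }
      dat
    })
  }
  new_polys <- list()
  for (i in seq_along(polygons)) {
    p <- rotate_points(polygons[[i]], params$rotation, w / 2, h / 2)
    if (all(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h)) {
      warning("polygon ", i, " rotated fully out of frame; dropped")
    } else {
      new_polys <- c(new_polys, list(p))
    }
  }
  res <- if (inherits(image, "Image")) {
    EBImage::Image(dat, colormode = EBImage::colorMode(out))
  } else {
    dat
  }
  list(image = res, polygons = new_polys, params = params)
}
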