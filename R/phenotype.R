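#' Pixel-to-physical calibration
#'
#' The imaging geometry is summarised by the physical length the image
#' width spans. The reference setup images a 250 mm wide scene at 1800 px;
#' square pixels are assumed, so the same mm/px scale applies vertically.
#'
#' @param img_width_px image width in pixels (> 0).
#' @param physical_width_mm physical width of the imaged scene in mm
#'   (> 0, default 250).
#' @return a `calibration` list.
#' @export
calibration <- function(img_width_px = 1800, physical_width_mm = 250) {
  if (img_width_px <= 0 || physical_width_mm <= 0) {
    stop("calibration dimensions must be strictly positive")
  }
  structure(list(img_width_px = img_width_px,
                 physical_width_mm = physical_width_mm),
            class = "calibration")
}

#' Physical area represented by one pixel
#'
#' `(physical_width_mm / img_width_px)^2`, in mm^2 per pixel.
#'
#' @param cal a [calibration()].
#' @return mm^2 per pixel.
#' @export
pixel_area <- function(cal = calibration()) {
  (cal$physical_width_mm / cal$img_width_px)^2
}

#' Calibrated leaf area from a foreground pixel count
#'
#' `pixel_area(cal) * sum_pixel`, in mm^2. Vectorised over `sum_pixel`.
#'
#' @param sum_pixel non-negative foreground pixel count(s).
#' @param cal a [calibration()].
#' @return leaf area(s) in mm^2.
#' @export
leaf_area <- function(sum_pixel, cal = calibration()) {
  if (any(sum_pixel < 0)) stop("negative pixel count")
  pixel_area(cal) * sum_pixel
}

#' Per-leaf calibrated area series from tracked observations
#'
#' @param tracks_df per-observation table from [tracks_to_df()], with a
#'   `time` column.
#' @param cal a [calibration()].
#' @return data frame `leaf_id`, `time`, `t_h` (hours since the first
#'   observation in the table), `pixel_count`, `area_mm2`, ordered by leaf
#'   then time.
#' @export
area_series <- function(tracks_df, cal = calibration()) {
  stopifnot(all(c("leaf_id", "time", "pixel_count") %in% names(tracks_df)))
  df <- tracks_df[order(tracks_df$leaf_id, tracks_df$time), ]
  df$t_h <- interval_hours(min(df$time), df$time)
  df$area_mm2 <- leaf_area(df$pixel_count, cal)
  rownames(df) <- NULL
  keep <- c("leaf_id", "time", "t_h", "pixel_count", "area_mm2",
            intersect(c("cx", "cy"), names(df)))
  df[keep]
}

#' Real-time leaf growth rate from an area series
#'
#' For each observation, `(Area_current - Area_previous) / (t_i - t_(i-1))`
#' in mm^2/h. The comparison window is either a lag of `window` frames
#' (default 1: consecutive frames) or, when `hours` is given, the most
#' recent observation at least `hours` earlier — the window is not limited
#' to consecutive frames. Negative rates (segmentation noise) are reported
#' as computed unless `clamp_negative = TRUE`.
#'
#' @param series data frame from [area_series()] (needs `leaf_id`, `time`,
#'   `area_mm2`).
#' @param window integer frame lag (ignored when `hours` is set).
#' @param hours optional time span in hours defining the window.
#' @param clamp_negative replace negative rates with 0 (off by default).
#' @return data frame `leaf_id`, `time`, `t_h`, `dt_h`, `rate_mm2_per_h`;
#'   leaves with fewer than two observations contribute no rows.
#' @export
growth_rate <- function(series, window = 1L, hours = NULL,
                        clamp_negative = FALSE) {
  stopifnot(all(c("leaf_id", "time", "area_mm2") %in% names(series)))
  if (is.null(hours)) stopifnot(window >= 1)
  t0 <- min(series$time)
  out <- lapply(split(series, series$leaf_id), function(s) {
    s <- s[order(s$time), ]
    n <- nrow(s)
    if (n < 2) return(NULL)
    if (is.null(hours)) {
      cur <- seq_len(n)[-(seq_len(min(window, n)))]
      prev <- cur - window
    } else {
      th <- interval_hours(t0, s$time)
      prev <- vapply(seq_len(n), function(i) {
        ok <- which(th <= th[i] - hours)
        if (length(ok)) max(ok) else NA_integer_
      }, integer(1))
      cur <- which(!is.na(prev))
      prev <- prev[cur]
    }
    if (!length(cur)) return(NULL)
    dt <- interval_hours(s$time[prev], s$time[cur])
    if (any(dt <= 0)) stop("zero or negative elapsed time in growth window")
    rate <- (s$area_mm2[cur] - s$area_mm2[prev]) / dt
    if (clamp_negative) rate <- pmax(rate, 0)
    data.frame(leaf_id = s$leaf_id[cur], time = s$time[cur],
               t_h = interval_hours(t0, s$time[cur]),
               dt_h = dt, rate_mm2_per_h = rate)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(leaf_id = integer(0), time = as.POSIXct(character(0)),
                      t_h = numeric(0), dt_h = numeric(0),
                      rate_mm2_per_h = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-box aggregation: mean area and mean growth rate at a time point
#'
#' Averages over the planted grid leaves (ids 0..15 by default): for each
#' leaf the observation at, or nearest before, the query time contributes.
#' Late extra identifiers (tracks opened beyond the grid) are excluded.
#'
#' @param area data frame from [area_series()].
#' @param rate optional data frame from [growth_rate()].
#' @param at query time (`POSIXct` or a "YYYY-MM-DD-HH-MM-SS" string).
#' @param ids leaf identifiers included in the box mean (default `0:15`).
#' @return list with `mean_area_mm2`, `n_area`, and (when `rate` is given)
#'   `mean_rate_mm2_per_h`, `n_rate`.
#' @export
aggregate_box <- function(area, rate = NULL, at, ids = 0:15) {
  if (is.character(at)) at <- parse_timestamp(at)
  pick <- function(df, col) {
    df <- df[df$leaf_id %in% ids & df$time <= at, ]
    if (!nrow(df)) return(numeric(0))
    vapply(split(df, df$leaf_id),
           function(s) s[[col]][which.max(as.numeric(s$time))], numeric(1))
  }
  a <- pick(area, "area_mm2")
  if (!length(a)) stop("no contributing leaves at or before the query time")
  out <- list(mean_area_mm2 = mean(a), n_area = length(a))
  if (!is.null(rate)) {
    r <- pick(rate, "rate_mm2_per_h")
    out$mean_rate_mm2_per_h <- if (length(r)) mean(r) else NA_real_
    out$n_rate <- length(r)
  }
  out
}

#' Assemble the per-leaf results table written by [write_results_csv()]
#'
#' @param area data frame from [area_series()].
#' @param rate data frame from [growth_rate()] (rates are merged on
#'   `leaf_id` + `time`; observations without a rate get `NA`).
#' @return data frame in the results-CSV column order.
#' @export
phenotype_table <- function(area, rate = NULL) {
  out <- data.frame(frame_time = area$time, leaf_id = area$leaf_id,
                    cx = if (is.null(area$cx)) NA_real_ else area$cx,
                    cy = if (is.null(area$cy)) NA_real_ else area$cy,
                    pixel_count = area$pixel_count, area_mm2 = area$area_mm2,
                    growth_rate_mm2_per_h = NA_real_)
  if (!is.null(rate) && nrow(rate)) {
    key <- paste(out$leaf_id, as.numeric(out$frame_time))
    rkey <- paste(rate$leaf_id, as.numeric(rate$time))
    out$growth_rate_mm2_per_h <- rate$rate_mm2_per_h[match(key, rkey)]
  }
  out
}
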