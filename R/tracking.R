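#' Matching configuration for cross-frame label tracing
#'
#' @param iou_threshold IoU an instance must *exceed* (strict `>`) against a
#'   live track's most recent mask to inherit its identifier. Default 0.5.
#' @param rows,cols planting-grid layout used for initial identifier
#'   assignment. Default 4 x 4 (16 leaves).
#' @return a `match_config` list.
#' @export
match_config <- function(iou_threshold = 0.5, rows = 4L, cols = 4L) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1, rows >= 1, cols >= 1)
  structure(list(iou_threshold = iou_threshold,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "match_config")
}

#' Intersection over Union of two masks
#'
#' `|A intersect B| / |A union B|` over foreground pixel sets. Accepts
#' binary mask matrices or [instance_mask()] objects (for which only the
#' bounding-box overlap region is visited).
#'
#' @param a,b masks of equal frame dimensions, at least one non-empty.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (is.matrix(a)) a <- if (any(a > 0)) instance_mask(a) else NULL
  if (is.matrix(b)) b <- if (any(b > 0)) instance_mask(b) else NULL
  if (is.null(a) && is.null(b)) stop("IoU undefined: both masks empty")
  if (is.null(a) || is.null(b)) return(0)
  if (!identical(a$dim, b$dim)) stop("mask dimension mismatch")
  x0 <- max(a$bbox[1], b$bbox[1]); x1 <- min(a$bbox[3], b$bbox[3])
  y0 <- max(a$bbox[2], b$bbox[2]); y1 <- min(a$bbox[4], b$bbox[4])
  inter <- 0L
  if (x1 >= x0 && y1 >= y0) {
    ca <- a$crop[(y0 - a$bbox[2] + 1L):(y1 - a$bbox[2] + 1L),
                 (x0 - a$bbox[1] + 1L):(x1 - a$bbox[1] + 1L), drop = FALSE]
    cb <- b$crop[(y0 - b$bbox[2] + 1L):(y1 - b$bbox[2] + 1L),
                 (x0 - b$bbox[1] + 1L):(x1 - b$bbox[1] + 1L), drop = FALSE]
    inter <- sum(ca & cb)
  }
  inter / (a$pixel_count + b$pixel_count - inter)
}

#' Grid-based initial identifier assignment
#'
#' First-frame rule for a planted `rows x cols` grid: instances are sorted
#' by centroid `cy` and chunked into `rows` groups of `cols`; within each
#' group (one planting row) instances are ordered left to right by centroid
#' `cx`. Identifiers `0 .. rows*cols - 1` are assigned row-major.
#'
#' @param instances list of [instance_mask()] objects; length must equal
#'   `rows * cols`.
#' @param config a [match_config()].
#' @return integer vector of leaf ids aligned with `instances`.
#' @export
assign_initial_ids <- function(instances, config = match_config()) {
  n_exp <- config$rows * config$cols
  if (length(instances) != n_exp) {
    stop("expected ", n_exp, " instances in the initial frame, got ",
         length(instances), "; review the first frame manually")
  }
  cx <- vapply(instances, function(i) i$centroid[["cx"]], numeric(1))
  cy <- vapply(instances, function(i) i$centroid[["cy"]], numeric(1))
  ids <- integer(n_exp)
  by_row <- split(order(cy), rep(seq_len(config$rows), each = config$cols))
  next_id <- 0L
  for (grp in by_row) {
    for (j in grp[order(cx[grp])]) {
      ids[j] <- next_id
      next_id <- next_id + 1L
    }
  }
  ids
}

new_track <- function(leaf_id, time, inst, frame_idx) {
  structure(list(leaf_id = leaf_id,
                 times = if (is.null(time)) numeric(0) else time,
                 frames = frame_idx,
                 observations = list(inst),
                 last = inst),
            class = "leaf_track")
}

append_obs <- function(track, time, inst, frame_idx) {
  if (length(track$times) && !is.null(time) &&
      time <= track$times[length(track$times)]) {
    stop("observation times must be strictly increasing within a track")
  }
  track$times <- c(track$times, time)
  track$frames <- c(track$frames, frame_idx)
  track$observations <- c(track$observations, list(inst))
  track$last <- inst
  track
}

#' Match one frame's instances against live tracks
#'
#' Every new instance is compared (mask IoU) with the most recent mask of
#' every live track. Assignments are made greedily in descending IoU; an
#' instance inherits a track's identifier only when the IoU strictly
#' exceeds `config$iou_threshold`, and no track receives two instances from
#' the same frame. Unmatched instances open fresh tracks with identifiers
#' beyond the grid range. Unmatched tracks stay live indefinitely (a leaf
#' may be temporarily missed by the detector).
#'
#' @param tracks list of tracks from [assign_initial_ids()] /
#'   [track_series()].
#' @param frame a `frame_observation` (see [load_instances()]).
#' @param config a [match_config()].
#' @param frame_idx integer frame index recorded with each observation.
#' @return updated list of tracks.
#' @export
match_frame <- function(tracks, frame, config = match_config(),
                        frame_idx = NA_integer_) {
  insts <- frame$instances
  if (length(insts) == 0) return(tracks)
  n_i <- length(insts); n_t <- length(tracks)
  iou <- matrix(0, n_i, n_t)
  for (i in seq_len(n_i)) for (j in seq_len(n_t)) {
    iou[i, j] <- mask_iou(insts[[i]], tracks[[j]]$last)
  }
  inst_free <- rep(TRUE, n_i); track_free <- rep(TRUE, n_t)
  repeat {
    live <- outer(inst_free, track_free, `&`)
    if (!any(live & iou > config$iou_threshold)) break
    cand <- iou; cand[!live] <- -1
    best <- arrayInd(which.max(cand), dim(cand))
    i <- best[1]; j <- best[2]
    tracks[[j]] <- append_obs(tracks[[j]], frame$time, insts[[i]], frame_idx)
    inst_free[i] <- FALSE; track_free[j] <- FALSE
  }
  next_id <- max(vapply(tracks, `[[`, integer(1), "leaf_id")) + 1L
  for (i in which(inst_free)) {
    tracks <- c(tracks, list(new_track(next_id, frame$time, insts[[i]],
                                       frame_idx)))
    next_id <- next_id + 1L
  }
  tracks
}

#' Track leaf identities through a frame sequence
#'
#' Initialises identifiers on the first frame with the grid rule
#' ([assign_initial_ids()]) and propagates them through all subsequent
#' frames by IoU inheritance ([match_frame()]).
#'
#' @param frames list of `frame_observation`s in chronological order.
#' @param config a [match_config()].
#' @return list of `leaf_track`s, ordered by `leaf_id`.
#' @export
track_series <- function(frames, config = match_config()) {
  stopifnot(length(frames) >= 1)
  first <- frames[[1]]
  ids <- assign_initial_ids(first$instances, config)
  tracks <- lapply(order(ids), function(i) {
    new_track(ids[i], first$time, first$instances[[i]], 1L)
  })
  for (k in seq_along(frames)[-1]) {
    tracks <- match_frame(tracks, frames[[k]], config, frame_idx = k)
  }
  tracks[order(vapply(tracks, `[[`, integer(1), "leaf_id"))]
}

#' Flatten tracks into a per-observation table
#'
#' @param tracks list of `leaf_track`s.
#' @return data frame with columns `leaf_id`, `frame`, `time` (`POSIXct`,
#'   absent when frames carried no timestamps), `cx`, `cy`, `pixel_count`.
#' @export
tracks_to_df <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$observations)
    data.frame(
      leaf_id = rep(tr$leaf_id, n),
      frame = if (length(tr$frames)) tr$frames else rep(NA_integer_, n),
      time = if (length(tr$times)) as.POSIXct(tr$times, tz = "UTC",
                                              origin = "1970-01-01")
             else rep(as.POSIXct(NA), n),
      cx = vapply(tr$observations, function(o) o$centroid[["cx"]], numeric(1)),
      cy = vapply(tr$observations, function(o) o$centroid[["cy"]], numeric(1)),
      pixel_count = vapply(tr$observations, `[[`, integer(1), "pixel_count")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.leaf_track <- function(x, ...) {
  cat(sprintf("leaf_track %d: %d observation(s)\n",
              x$leaf_id, length(x$observations)))
  invisible(x)
}
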