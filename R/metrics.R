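#' Match predicted masks to ground truth at an IoU threshold
#'
#' Greedy confidence-ordered assignment: predictions are visited in
#' descending confidence; each claims its highest-IoU *unmatched* ground
#' truth when that IoU is at least `iou_thresh` (a true positive),
#' otherwise it is a false positive. Ground truths left unclaimed are false
#' negatives. Mask (pixel-set) IoU is used throughout.
#'
#' @param gt list of ground-truth masks (binary matrices or
#'   [instance_mask()]s).
#' @param pred list of predicted masks (same representations).
#' @param confidence numeric vector, one score per prediction.
#' @param iou_thresh IoU threshold in `(0, 1]`.
#' @return an `eval_match`: `tp`, `fp`, `fn` counts plus a `detections`
#'   data frame (`confidence`, `tp` flag, `matched_gt` 1-based index or
#'   `NA`) ordered by descending confidence — the input to [pr_curve()].
#' @export
match_predictions <- function(gt, pred, confidence, iou_thresh = 0.5) {
  stopifnot(length(pred) == length(confidence), iou_thresh > 0,
            iou_thresh <= 1)
  as_inst <- function(m) if (is.matrix(m)) instance_mask(m) else m
  gt <- lapply(gt, as_inst)
  pred <- lapply(pred, as_inst)
  ord <- order(confidence, decreasing = TRUE)
  gt_free <- rep(TRUE, length(gt))
  det <- data.frame(confidence = confidence[ord],
                    tp = logical(length(ord)),
                    matched_gt = rep(NA_integer_, length(ord)))
  for (r in seq_along(ord)) {
    p <- pred[[ord[r]]]
    best_iou <- -1; best_j <- NA_integer_
    for (j in which(gt_free)) {
      v <- mask_iou(p, gt[[j]])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (!is.na(best_j) && best_iou >= iou_thresh) {
      det$tp[r] <- TRUE
      det$matched_gt[r] <- best_j
      gt_free[best_j] <- FALSE
    }
  }
  structure(list(tp = sum(det$tp), fp = sum(!det$tp),
                 fn = sum(gt_free), n_gt = length(gt),
                 detections = det),
            class = "eval_match")
}

#' @export
print.eval_match <- function(x, ...) {
  cat(sprintf("eval_match: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. A zero
#' denominator makes the corresponding statistic undefined (`NA`), never 0.
#'
#' @param m an `eval_match` (or any list with `tp`, `fp`, `fn`).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
        else NA_real_
  c(precision = p, recall = r, f1 = f1)
}

#' Precision-recall curve from confidence-ranked detections
#'
#' Sweeps the confidence ranking: after the k highest-confidence
#' detections, `recall = cumTP/n_gt` and `precision = cumTP/k`.
#'
#' @param match an `eval_match` from [match_predictions()], or a data
#'   frame like its `detections` (with `confidence` and `tp`).
#' @param n_gt number of ground-truth instances (taken from the
#'   `eval_match` when available).
#' @return data frame `recall`, `precision` (recall non-decreasing).
#' @export
pr_curve <- function(match, n_gt = NULL) {
  det <- if (is.data.frame(match)) match else match$detections
  if (is.null(n_gt)) n_gt <- match$n_gt
  stopifnot(!is.null(n_gt), n_gt > 0)
  det <- det[order(det$confidence, decreasing = TRUE), ]
  cum_tp <- cumsum(det$tp)
  data.frame(recall = cum_tp / n_gt,
             precision = cum_tp / seq_len(nrow(det)))
}

#' Average precision by all-point interpolation
#'
#' Area under the precision envelope over recall in `[0, 1]`: precision is
#' replaced by its monotone non-increasing hull from the right (the
#' convention of modern detection toolkits), and the area is the sum of
#' `delta-recall * envelope-precision` rectangles.
#'
#' @param curve data frame with `recall` and `precision` columns, sorted by
#'   the confidence sweep (recall non-decreasing).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  if (!nrow(curve)) stop("empty precision-recall curve")
  stopifnot(all(c("recall", "precision") %in% names(curve)),
            all(diff(curve$recall) >= 0))
  env <- rev(cummax(rev(curve$precision)))
  sum(diff(c(0, curve$recall)) * env)
}

#' mAP50 and mAP50-95 from per-threshold average precisions
#'
#' With a single class the class mean collapses: `mAP50` is the AP at IoU
#' 0.50. `mAP50-95` is the arithmetic mean of the APs at the ten thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @param aps_by_threshold named numeric vector of APs; names are IoU
#'   thresholds (e.g. `"0.5"`).
#' @param range compute mAP50-95 (requires all ten thresholds).
#' @return named numeric vector `c(mAP50)` or `c(mAP50, mAP50_95)`.
#' @export
map_range <- function(aps_by_threshold, range = TRUE) {
  th <- round(as.numeric(names(aps_by_threshold)) * 100)
  if (!50 %in% th) stop("missing AP at IoU threshold 0.50")
  out <- c(mAP50 = unname(aps_by_threshold[match(50, th)]))
  if (range) {
    need <- seq(50, 95, by = 5)
    miss <- setdiff(need, th)
    if (length(miss)) {
      stop("missing AP at IoU threshold(s): ",
           paste(sprintf("%.2f", miss / 100), collapse = ", "))
    }
    out <- c(out,
             mAP50_95 = mean(aps_by_threshold[match(need, th)]))
  }
  out
}

#' Convolution-layer FLOPs and parameter count
#'
#' `FLOPs = 2 * H * W * (C_in * K^2 + 1) * C_out` (the `+1` is the bias
#' term) and `Params = C_in * K^2 * C_out` (weights only, as conventionally
#' reported).
#'
#' @param h,w feature-map height and width.
#' @param c_in,c_out input / output channel counts.
#' @param k kernel side length (`k^2` is the kernel area).
#' @return named numeric vector `c(flops, params)`.
#' @export
conv_flops_params <- function(h, w, c_in, c_out, k) {
  v <- c(h, w, c_in, c_out, k)
  if (any(v <= 0) || any(v != round(v))) {
    stop("all layer dimensions must be strictly positive integers")
  }
  c(flops = 2 * h * w * (c_in * k^2 + 1) * c_out,
    params = c_in * k^2 * c_out)
}

#' End-to-end segmentation evaluation over an IoU threshold range
#'
#' Runs [match_predictions()] and [average_precision()] at each threshold
#' and summarises P/R/F1 at 0.50 together with mAP50 and mAP50-95.
#'
#' @inheritParams match_predictions
#' @param thresholds IoU thresholds (default 0.50..0.95 step 0.05).
#' @return list: `ap_by_threshold`, `mAP50`, `mAP50_95`, `precision`,
#'   `recall`, `f1` (the last three at threshold 0.50).
#' @export
evaluate_segmentation <- function(gt, pred, confidence,
                                  thresholds = seq(0.5, 0.95, by = 0.05)) {
  aps <- numeric(0)
  prf <- NULL
  for (t in thresholds) {
    m <- match_predictions(gt, pred, confidence, iou_thresh = t)
    ap <- if (m$n_gt == 0) NA_real_ else average_precision(pr_curve(m))
    aps <- c(aps, stats::setNames(ap, format(t)))
    if (abs(t - 0.5) < 1e-9) prf <- precision_recall_f1(m)
  }
  mm <- map_range(aps, range = length(thresholds) == 10)
  list(ap_by_threshold = aps,
       mAP50 = unname(mm["mAP50"]),
       mAP50_95 = if ("mAP50_95" %in% names(mm)) unname(mm["mAP50_95"])
                  else NA_real_,
       precision = unname(prf["precision"]),
       recall = unname(prf["recall"]),
       f1 = unname(prf["f1"]))
}
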