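# Joint IoU / localization-error detection evaluation: per-pair scores,
# the TP/FP/FN outcome rule with the LE rescue clause, multi-annotator
# averaging, recall/precision/F1, and recall-threshold curves.

#' Intersection over union of two boxes
#'
#' Vectorized: `a` and `b` may be single `bbox` objects or data frames of
#' boxes (columns `x`, `y`, `w`, `h`) with matching or broadcastable rows.
#'
#' @param a,b Boxes (see [bbox_tbl()]).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- bbox_tbl(a); b <- bbox_tbl(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  if (any(a$w <= 0 | a$h <= 0 | b$w <= 0 | b$h <= 0)) {
    abort("zero-area box passed to box_iou")
  }
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' Localization error between ground-truth and detection boxes
#'
#' The Euclidean composite of center offset and size mismatch,
#' `sqrt((xc_gt-xc_d)^2 + (yc_gt-yc_d)^2 + (w_gt-w_d)^2 + (h_gt-h_d)^2)`,
#' computed on normalized coordinates (x-terms divided by image width,
#' y-terms by height) so the value is dimensionless, scale-free, and the
#' conventional 0.1 true-positive threshold applies to any frame size.
#'
#' @param gt,det Boxes (see [bbox_tbl()]), vectorized like [box_iou()].
#' @param dims `c(height, width)` of the frame; required.
#' @return Numeric vector of LE values (>= 0; 0 iff the boxes coincide).
#' @export
box_le <- function(gt, det, dims) {
  if (missing(dims) || is.null(dims)) {
    abort("image dims are required: LE is defined on normalized coordinates")
  }
  g <- bbox_normalize(gt, dims); d <- bbox_normalize(det, dims)
  n <- max(nrow(g), nrow(d))
  if (nrow(g) == 1) g <- g[rep(1, n), ]
  if (nrow(d) == 1) d <- d[rep(1, n), ]
  sqrt((g$xc - d$xc)^2 + (g$yc - d$yc)^2 + (g$w - d$w)^2 + (g$h - d$h)^2)
}

#' Score one detection against one ground truth
#'
#' @param gt,det Boxes; `det = NULL` encodes a miss (no detection).
#' @param dims `c(height, width)`.
#' @return One-row tibble with `iou` and `le` (`NA` for a miss).
#' @export
score_detection <- function(gt, det, dims) {
  if (is.null(det)) return(tibble(iou = NA_real_, le = NA_real_))
  if (inherits(det, "detection")) det <- det$box
  tibble(iou = box_iou(gt, det), le = box_le(gt, det, dims))
}

#' Default thresholds of the joint IoU/LE outcome rule
#'
#' `iou_tp`: IoU strictly above this is a true positive on its own.
#' `le_tp`: LE strictly below this can rescue a sub-threshold IoU.
#' `iou_floor`: but only if IoU is at least this much — a low-IoU,
#' low-LE detection (similar size and position yet essentially no overlap)
#' is a false positive.
#'
#' @return Named list of the three thresholds.
#' @export
joint_thresholds <- function() list(iou_tp = 0.5, le_tp = 0.1, iou_floor = 0.25)

#' Classify detections as TP / FP / FN under the joint IoU + LE rule
#'
#' A missing detection (NA scores) is a false negative. A detection is a
#' true positive when `iou > iou_tp`, or when `le < le_tp` and
#' `iou >= iou_floor`; otherwise it is a false positive.
#'
#' @param scores Data frame with columns `iou` and `le` (NA row = miss), as
#'   produced by [score_detection()], or a single such pair.
#' @param thresholds List as from [joint_thresholds()].
#' @return Character vector of `"TP"`, `"FP"`, `"FN"`.
#' @export
joint_outcome <- function(scores, thresholds = joint_thresholds()) {
  s <- as_tibble(scores)
  dplyr::case_when(
    is.na(s$iou) | is.na(s$le) ~ "FN",
    s$iou > thresholds$iou_tp ~ "TP",
    s$le < thresholds$le_tp & s$iou >= thresholds$iou_floor ~ "TP",
    .default = "FP"
  )
}

#' Average IoU/LE scores over annotators for one image
#'
#' @param scores_per_user Data frame with columns `iou`, `le`, one row per
#'   annotator.
#' @return One-row tibble with the arithmetic means.
#' @export
per_image_mean <- function(scores_per_user) {
  s <- as_tibble(scores_per_user)
  if (nrow(s) == 0) abort("per_image_mean needs at least one annotator score")
  tibble(iou = mean(s$iou), le = mean(s$le))
}

#' Dataset-level summary of per-image scores
#'
#' @param per_image Data frame with columns `iou`, `le`, one row per image.
#' @return One-row tibble: mean and sample standard deviation (n-1
#'   denominator) of each metric; for a single image the sd is reported as
#'   0 with `sd_defined = FALSE`.
#' @export
dataset_summary <- function(per_image) {
  s <- as_tibble(per_image)
  if (nrow(s) == 0) abort("dataset_summary needs at least one image")
  one <- nrow(s) == 1
  tibble(
    n = nrow(s),
    iou_mean = mean(s$iou), iou_sd = if (one) 0 else sd(s$iou),
    le_mean = mean(s$le), le_sd = if (one) 0 else sd(s$le),
    sd_defined = !one
  )
}

#' Recall, precision and F1 from outcome counts
#'
#' Recall is `TP / (TP + FN)`; when no false negatives were recorded it
#' falls back to `TP / N` with `N` the total number of ground truths.
#' Ratios with zero denominator are reported as 0 by convention.
#'
#' @param tp,fp,fn Outcome counts.
#' @param n_ground_truths Total ground truths `N` (used when `fn == 0`).
#' @return One-row tibble with `recall`, `precision`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn, n_ground_truths = tp + fn) {
  if (tp + fp + fn == 0 && n_ground_truths == 0) {
    abort("all outcome counts are zero")
  }
  recall <- if (fn == 0) {
    if (n_ground_truths > 0) tp / n_ground_truths else 0
  } else tp / (tp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(recall = recall, precision = precision, f1 = f1)
}

#' Recall as a function of the decision threshold
#'
#' For the IoU curve a detection counts as true positive at threshold `t`
#' when its IoU exceeds `t` (recall is non-increasing in `t`); for the LE
#' curve when its LE is below `t` (recall non-decreasing in `t`). Missing
#' detections never count.
#'
#' @param scores Data frame with columns `iou` and `le` (NA = miss), one
#'   row per evaluated ground truth.
#' @param metric `"iou"` or `"le"`.
#' @param thresholds Sorted threshold grid (default `seq(0, 1, 0.05)`).
#' @return A `recall_curve` tibble with columns `metric`, `threshold`,
#'   `recall`.
#' @export
recall_curve <- function(scores, metric = c("iou", "le"),
                         thresholds = seq(0, 1, 0.05)) {
  metric <- match.arg(metric)
  s <- as_tibble(scores)
  n <- nrow(s)
  vals <- s[[metric]]
  rec <- vapply(thresholds, function(t) {
    if (n == 0) return(0)
    hits <- if (metric == "iou") vals > t else vals < t
    sum(hits, na.rm = TRUE) / n
  }, numeric(1))
  out <- tibble(metric = metric, threshold = thresholds, recall = rec)
  class(out) <- c("recall_curve", class(out))
  out
}

#' @method autoplot recall_curve
#' @export
autoplot.recall_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$threshold, .data$recall,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "score threshold", y = "recall",
                  title = "Recall-threshold characteristic") +
    ggplot2::theme_minimal()
}

#' Evaluate one detection per image against multi-annotator ground truth
#'
#' The full per-image protocol: each annotator's box is scored against the
#' detection, outcomes are assigned per annotator under the joint rule and
#' pooled into counts, while per-image IoU/LE are the across-annotator
#' means.
#'
#' @param detections List (one element per image) of `bbox`/`detection` or
#'   `NULL` for a miss.
#' @param gt_boxes List (one element per image) of a single `bbox` or a
#'   list of annotator `bbox`es.
#' @param dims `c(height, width)` shared by all images.
#' @param thresholds Joint rule thresholds.
#' @return List with `per_image` (tibble of mean scores + outcome of the
#'   mean), `counts` (tp/fp/fn tibble over all annotator outcomes),
#'   `summary` ([dataset_summary()] output) and `metrics`
#'   ([precision_recall_f1()] output).
#' @export
evaluate_detections <- function(detections, gt_boxes, dims,
                                thresholds = joint_thresholds()) {
  stopifnot(length(detections) == length(gt_boxes))
  rows <- purrr::map2_dfr(seq_along(detections), gt_boxes,
    function(i, gts) {
      if (inherits(gts, "bbox")) gts <- list(gts)
      det <- detections[[i]]
      purrr::imap_dfr(gts, function(g, u) {
        s <- score_detection(g, det, dims)
        tibble(image = i, user = u, iou = s$iou, le = s$le)
      })
    })
  rows$outcome <- joint_outcome(rows[, c("iou", "le")], thresholds)
  per_image <- rows |>
    dplyr::group_by(.data$image) |>
    dplyr::summarise(iou = mean(.data$iou), le = mean(.data$le),
                     .groups = "drop")
  counts <- tibble(
    tp = sum(rows$outcome == "TP"),
    fp = sum(rows$outcome == "FP"),
    fn = sum(rows$outcome == "FN"),
    n_ground_truths = nrow(rows)
  )
  scored <- dplyr::filter(per_image, !is.na(.data$iou))
  list(
    per_image = per_image,
    counts = counts,
    summary = if (nrow(scored) > 0) dataset_summary(scored) else NULL,
    metrics = precision_recall_f1(counts$tp, counts$fp, counts$fn,
                                  counts$n_ground_truths)
  )
}
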