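#' Detection evaluation: matching, precision/recall, AP and mAP
#'
#' The evaluation protocol behind the reported metrics:
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `AP = integral of the precision envelope over recall` (all-points
#' interpolation), `mAP = mean of per-class APs`; mAP50 uses IoU 0.5 and
#' mAP50-95 averages the ten thresholds 0.50, 0.55, ..., 0.95.
#'
#' Matching is greedy and one-to-one per class: detections in descending
#' score order each claim the highest-IoU unmatched ground truth with IoU
#' at or above the threshold; unmatched detections are false positives,
#' unmatched ground truths false negatives.
#'
#' @name evaluation
NULL

# dets: data.frame(image, class_id, score, x1, y1, x2, y2)
# gts:  data.frame(image, class_id, x1, y1, x2, y2)

#' Match detections to ground truth and count TP/FP/FN
#'
#' @param dets Detections data.frame (`image`, `class_id`, `score`, box
#'   columns `x1`, `y1`, `x2`, `y2`).
#' @param gts Ground-truth data.frame (same box columns, no score).
#' @param iou_thresh Matching IoU threshold.
#' @return Data.frame with one row per class present in either input:
#'   `class_id`, `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  rows <- lapply(classes, function(cl) {
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    flags <- match_flags(dc, gc, iou_thresh)
    data.frame(class_id = cl, tp = sum(flags$tp), fp = sum(!flags$tp),
               fn = nrow(gc) - sum(flags$tp))
  })
  if (length(rows) == 0L)
    return(data.frame(class_id = integer(), tp = integer(),
                      fp = integer(), fn = integer()))
  do.call(rbind, rows)
}

# per-detection TP flags (score-descending order), one class, image-aware
match_flags <- function(dc, gc, iou_thresh) {
  if (is.null(dc$image)) dc$image <- rep(1L, nrow(dc))
  if (is.null(gc$image)) gc$image <- rep(1L, nrow(gc))
  if (nrow(dc) == 0L)
    return(list(tp = logical(), order = integer(), scores = numeric()))
  ord <- order(-dc$score)
  dc <- dc[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gc))
  tp <- logical(nrow(dc))
  for (i in seq_len(nrow(dc))) {
    cand <- which(!used & gc$image == dc$image[i])
    if (length(cand) == 0L) next
    ious <- box_iou(as.matrix(dc[i, c("x1", "y1", "x2", "y2")]),
                    as.matrix(gc[cand, c("x1", "y1", "x2", "y2")]))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  list(tp = tp, order = ord, scores = dc$score)
}

#' Precision and recall from confusion counts
#'
#' Conventions: precision is 1 when there are no predictions
#' (`TP + FP = 0`); recall is 0 when there are no ground truths.
#'
#' @param counts Data.frame with `tp`, `fp`, `fn` columns (rows are
#'   summed).
#' @return Named vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r)
}

#' Precision-recall curve of one class
#'
#' @param dets,gts Single-class detection / ground-truth data.frames.
#' @param iou_thresh Matching IoU.
#' @return Data.frame with `score`, `recall`, `precision` (one row per
#'   detection, score-descending).
#' @export
pr_curve <- function(dets, gts, iou_thresh = 0.5) {
  flags <- match_flags(dets, gts, iou_thresh)
  n_gt <- nrow(gts)
  if (length(flags$tp) == 0L)
    return(data.frame(score = numeric(), recall = numeric(),
                      precision = numeric()))
  ctp <- cumsum(flags$tp)
  cfp <- cumsum(!flags$tp)
  data.frame(score = flags$scores,
             recall = if (n_gt > 0) ctp / n_gt else rep(0, length(ctp)),
             precision = ctp / (ctp + cfp))
}

#' Average precision from a precision-recall curve
#'
#' All-points interpolation: the precision at each recall level is
#' replaced by the maximum precision at any equal-or-higher recall, and
#' the area under this envelope is accumulated over the recall increments.
#'
#' @param curve Data.frame from [pr_curve()].
#' @return AP in `[0, 1]`.
#' @export
ap_from_curve <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  r <- c(0, curve$recall)
  p <- c(0, curve$precision)
  # envelope: running max from the right
  env <- rev(cummax(rev(p)))
  sum(diff(r) * env[-1])
}

#' Per-class AP table and mAP
#'
#' @param dets,gts Full detection / ground-truth data.frames.
#' @param iou_thresh IoU threshold (scalar) for `class_ap_table`.
#' @param n_classes Total class count (classes without ground truth are
#'   excluded from the mean).
#' @return `class_ap_table`: data.frame `class_id`, `ap`, `n_gt` plus
#'   attribute-free list; `map50` / `map50_95`: list with `per_class`
#'   and `map`.
#' @export
class_ap_table <- function(dets, gts, iou_thresh = 0.5, n_classes = 3L) {
  rows <- lapply(0:(n_classes - 1L), function(cl) {
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    if (nrow(gc) == 0L)
      return(data.frame(class_id = cl, ap = NA_real_, n_gt = 0L))
    data.frame(class_id = cl,
               ap = ap_from_curve(pr_curve(dc, gc, iou_thresh)),
               n_gt = nrow(gc))
  })
  do.call(rbind, rows)
}

#' @rdname class_ap_table
#' @export
map50 <- function(dets, gts, n_classes = 3L) {
  tab <- class_ap_table(dets, gts, 0.5, n_classes)
  list(per_class = tab, map = mean(tab$ap, na.rm = TRUE))
}

#' @rdname class_ap_table
#' @export
map50_95 <- function(dets, gts, n_classes = 3L) {
  ths <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(ths, function(th)
    mean(class_ap_table(dets, gts, th, n_classes)$ap, na.rm = TRUE),
    numeric(1))
  list(per_threshold = data.frame(iou = ths, map = aps), map = mean(aps))
}

#' F1-confidence curve
#'
#' Sweeps a confidence-threshold grid; at each threshold the macro-average
#' F1 over classes is computed from the confusion counts at IoU 0.5.
#'
#' @param dets,gts Detection / ground-truth data.frames.
#' @param grid Confidence thresholds to evaluate.
#' @param iou_thresh Matching IoU.
#' @param n_classes Class count for the macro average.
#' @return List with `curve` (data.frame `threshold`, `f1`), `best_f1`
#'   and `best_threshold`.
#' @export
f1_confidence_curve <- function(dets, gts, grid = seq(0.05, 0.95, 0.05),
                                iou_thresh = 0.5, n_classes = 3L) {
  stopifnot(all(grid > 0 & grid < 1))
  f1s <- vapply(grid, function(th) {
    keep <- dets[dets$score >= th, , drop = FALSE]
    per <- vapply(0:(n_classes - 1L), function(cl) {
      gc <- gts[gts$class_id == cl, , drop = FALSE]
      dc <- keep[keep$class_id == cl, , drop = FALSE]
      cnt <- match_detections(dc, gc, iou_thresh)
      pr <- precision_recall(cnt)
      if (pr[1] + pr[2] == 0) 0 else 2 * pr[1] * pr[2] / (pr[1] + pr[2])
    }, numeric(1))
    mean(per)
  }, numeric(1))
  best <- which.max(f1s)
  list(curve = data.frame(threshold = grid, f1 = f1s),
       best_f1 = f1s[best], best_threshold = grid[best])
}

#' Evaluate a detector on a labeled set
#'
#' @param dets,gts Detection and ground-truth data.frames.
#' @param n_classes Class count.
#' @return List with precision, recall (at IoU 0.5), mAP50, mAP50-95 and
#'   the per-class AP table.
#' @export
evaluate_detections <- function(dets, gts, n_classes = 3L) {
  cnt <- match_detections(dets, gts, 0.5)
  pr <- precision_recall(cnt)
  m50 <- map50(dets, gts, n_classes)
  m5095 <- map50_95(dets, gts, n_classes)
  list(precision = unname(pr[1]), recall = unname(pr[2]),
       map50 = m50$map, map50_95 = m5095$map,
       per_class = m50$per_class, counts = cnt)
}

#' Diagnostic plots
#'
#' Writes precision-recall and F1-confidence curves as PNG files using
#' base graphics.
#'
#' @param dets,gts Detection / ground-truth data.frames.
#' @param path Output PNG path.
#' @param n_classes Class count.
#' @return `path`, invisibly.
#' @export
plot_pr_curves <- function(dets, gts, path, n_classes = 3L) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", main = "Precision-Recall")
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  for (cl in 0:(n_classes - 1L)) {
    cur <- pr_curve(dets[dets$class_id == cl, , drop = FALSE],
                    gts[gts$class_id == cl, , drop = FALSE])
    if (nrow(cur))
      graphics::lines(cur$recall, cur$precision, col = cols[cl %% 3 + 1])
  }
  graphics::legend("bottomleft", legend = paste("class", 0:(n_classes - 1)),
                   col = cols[seq_len(n_classes) %% 3 + 1], lty = 1)
  invisible(path)
}

#' @rdname plot_pr_curves
#' @export
plot_f1_curve <- function(dets, gts, path, n_classes = 3L) {
  fc <- f1_confidence_curve(dets, gts, n_classes = n_classes)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(fc$curve$threshold, fc$curve$f1, type = "l",
                 xlab = "Confidence threshold", ylab = "Macro F1",
                 main = sprintf("best F1 %.3f @ %.3f", fc$best_f1,
                                fc$best_threshold))
  invisible(path)
}
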