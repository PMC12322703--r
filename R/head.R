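#' Decoupled detection head, box coding, assignment and loss
#'
#' One head per pyramid level (strides 8/16/32). Each head has two
#' parallel branches (classification and box regression); a branch is two
#' 3x3 convolution + batch-norm + ReLU layers followed by a plain 1x1
#' convolution. Box outputs are left/top/right/bottom distances from the
#' cell center in stride units, made non-negative with softplus;
#' classification outputs are per-class logits (scores are sigmoid
#' probabilities - there is no separate objectness branch).
#'
#' Decoding: cell (i, j) (0-based row/column) at stride s with distances
#' (l, t, r, b) produces the pixel box
#' `((j+0.5)s - l*s, (i+0.5)s - t*s, (j+0.5)s + r*s, (i+0.5)s + b*s)`,
#' clipped to the image. Per-class greedy NMS follows.
#'
#' Training assignment: a cell is positive when its center lies inside a
#' ground-truth box and within 2.5 stride units (per axis) of the box
#' center; ties go to the smallest-area box. Loss = binary cross-entropy
#' over all cell-class entries plus (1 - CIoU) over positives, weighted
#' 1:5, both normalized by the positive count (by the entry count when
#' there are no positives).
#'
#' @name detect_head
#' @keywords internal
NULL

head_new <- function(cfg) {
  pc <- pyramid_channels(cfg)
  cins <- c(pc[["c"]], pc[["b"]], pc[["a"]])
  bw <- cfg$head$branch_width
  ch <- list()
  for (i in 1:3) {
    for (br in c("cls", "box")) {
      out_ch <- if (br == "cls") cfg$n_classes else 4L
      p <- sprintf("p%d_%s_", i, br)
      ch[[paste0(p, "c1")]] <- layer_conv2d(3L, cins[i], bw[i], pad = 1L)
      ch[[paste0(p, "n1")]] <- layer_bn2d(bw[i])
      ch[[paste0(p, "c2")]] <- layer_conv2d(3L, bw[i], bw[i], pad = 1L)
      ch[[paste0(p, "n2")]] <- layer_bn2d(bw[i])
      ch[[paste0(p, "out")]] <- layer_conv2d(1L, bw[i], out_ch, pad = 0L)
    }
  }
  m <- new_module("head", children = ch)
  m$forward <- function(fused, training = TRUE) {
    # fused: list(C = stride 8, B = stride 16, A = stride 32)
    ins <- list(fused$C, fused$B, fused$A)
    strides <- c(8L, 16L, 32L)
    lapply(1:3, function(i) {
      branch <- function(br) {
        p <- sprintf("p%d_%s_", i, br)
        h <- ag_relu(ch[[paste0(p, "n1")]]$forward(
          ch[[paste0(p, "c1")]]$forward(ins[[i]], training), training))
        h <- ag_relu(ch[[paste0(p, "n2")]]$forward(
          ch[[paste0(p, "c2")]]$forward(h, training), training))
        ch[[paste0(p, "out")]]$forward(h, training)
      }
      list(box = ag_softplus(branch("box")), cls = branch("cls"),
           stride = strides[i])
    })
  }
  m
}

# ---- box utilities ---------------------------------------------------------

#' Intersection-over-union of two box sets
#'
#' @param a,b Matrices with columns x1, y1, x2, y2 (half-open pixel
#'   coordinates). Rows are recycled pairwise when one has a single row;
#'   otherwise the full cross IoU matrix is returned.
#' @return If both have >1 row, a `nrow(a) x nrow(b)` matrix; else a vector.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  x1 <- outer(a[, 1], b[, 1], pmax); y1 <- outer(a[, 2], b[, 2], pmax)
  x2 <- outer(a[, 3], b[, 3], pmin); y2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  un <- outer(area_a, area_b, "+") - inter
  m <- ifelse(un > 0, inter / un, 0)
  if (nrow(a) == 1L || nrow(b) == 1L) as.numeric(m) else m
}

# greedy per-class NMS; det is a data.frame sorted or not
nms_boxes <- function(det, iou_thresh) {
  if (nrow(det) == 0L) return(det)
  keep <- logical(nrow(det))
  for (cl in unique(det$class_id)) {
    idx <- which(det$class_id == cl)
    idx <- idx[order(-det$score[idx])]
    while (length(idx) > 0L) {
      i <- idx[1]
      keep[i] <- TRUE
      if (length(idx) == 1L) break
      rest <- idx[-1]
      ious <- box_iou(as.matrix(det[i, c("x1", "y1", "x2", "y2")]),
                      as.matrix(det[rest, c("x1", "y1", "x2", "y2")]))
      idx <- rest[ious <= iou_thresh]
    }
  }
  det[keep, , drop = FALSE]
}

#' Decode raw head maps into detections
#'
#' @param raw Per-scale raw output list as produced by the head forward
#'   pass (each element: `box`, `cls`, `stride`).
#' @param conf_thresh Minimum class probability.
#' @param nms_iou IoU threshold of per-class greedy non-maximum
#'   suppression.
#' @param img_size Image side in pixels (boxes are clipped to it).
#' @return A data.frame with columns `image`, `class_id`, `score`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @export
decode_detections <- function(raw, conf_thresh = 0.25, nms_iou = 0.5,
                              img_size = NULL) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, nms_iou >= 0, nms_iou <= 1)
  out <- list()
  n_img <- dim(raw[[1]]$box$v)[4]
  for (lv in raw) {
    s <- lv$stride
    bd <- lv$box$v; cd <- 1 / (1 + exp(-lv$cls$v))
    H <- dim(bd)[1]; W <- dim(bd)[2]; nc <- dim(cd)[3]
    cy <- (seq_len(H) - 0.5) * s
    cx <- (seq_len(W) - 0.5) * s
    for (n in seq_len(n_img)) {
      sc <- matrix(cd[, , , n], H * W, nc)
      best <- max.col(sc, ties.method = "first")
      bs <- sc[cbind(seq_len(H * W), best)]
      sel <- which(bs >= conf_thresh)
      if (length(sel) == 0L) next
      hh <- (sel - 1L) %% H + 1L
      ww <- (sel - 1L) %/% H + 1L
      l <- bd[cbind(hh, ww, 1L, n)]; t <- bd[cbind(hh, ww, 2L, n)]
      r <- bd[cbind(hh, ww, 3L, n)]; b <- bd[cbind(hh, ww, 4L, n)]
      x1 <- cx[ww] - l * s; y1 <- cy[hh] - t * s
      x2 <- cx[ww] + r * s; y2 <- cy[hh] + b * s
      if (!is.null(img_size)) {
        x1 <- pmax(0, x1); y1 <- pmax(0, y1)
        x2 <- pmin(img_size, x2); y2 <- pmin(img_size, y2)
      }
      ok <- x2 > x1 & y2 > y1
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        image = n, class_id = best[sel][ok] - 1L, score = bs[sel][ok],
        x1 = x1[ok], y1 = y1[ok], x2 = x2[ok], y2 = y2[ok])
    }
  }
  det <- if (length(out)) do.call(rbind, out)
         else data.frame(image = integer(), class_id = integer(),
                         score = numeric(), x1 = numeric(), y1 = numeric(),
                         x2 = numeric(), y2 = numeric())
  if (nrow(det)) {
    det <- do.call(rbind, lapply(split(det, det$image), nms_boxes,
                                 iou_thresh = nms_iou))
    rownames(det) <- NULL
  }
  det
}

# encode a pixel box as ltrb stride-unit distances at a given 0-based cell
encode_box <- function(box, i, j, stride) {
  cx <- (j + 0.5) * stride; cy <- (i + 0.5) * stride
  c(l = (cx - box[1]) / stride, t = (cy - box[2]) / stride,
    r = (box[3] - cx) / stride, b = (box[4] - cy) / stride)
}

# ---- assignment and loss ---------------------------------------------------

# targets: list (length N) of data.frames with class_id, x1, y1, x2, y2 in
# pixels. Returns per level: cls target array and positive-cell table.
assign_targets <- function(raw, targets, radius = 2.5) {
  lapply(raw, function(lv) {
    s <- lv$stride
    d <- dim(lv$cls$v); H <- d[1]; W <- d[2]; nc <- d[3]; N <- d[4]
    tgt <- array(0, dim = d)
    pos <- list()
    cy <- (seq_len(H) - 0.5) * s
    cx <- (seq_len(W) - 0.5) * s
    for (n in seq_len(N)) {
      gt <- targets[[n]]
      if (is.null(gt) || nrow(gt) == 0L) next
      area <- (gt$x2 - gt$x1) * (gt$y2 - gt$y1)
      assign <- matrix(0L, H, W)
      # larger boxes first so the smallest containing box wins
      for (k in order(area, decreasing = TRUE)) {
        gy <- cy >= gt$y1[k] & cy < gt$y2[k] &
          abs((gt$y1[k] + gt$y2[k]) / 2 - cy) <= radius * s
        gx <- cx >= gt$x1[k] & cx < gt$x2[k] &
          abs((gt$x1[k] + gt$x2[k]) / 2 - cx) <= radius * s
        if (any(gy) && any(gx)) assign[gy, gx] <- k
      }
      cells <- which(assign > 0L, arr.ind = TRUE)
      if (nrow(cells) == 0L) next
      ks <- assign[cells]
      tgt[cbind(cells[, 1], cells[, 2], gt$class_id[ks] + 1L,
                rep(n, nrow(cells)))] <- 1
      pos[[length(pos) + 1L]] <- cbind(cells[, 1], cells[, 2], n,
                                       gt$x1[ks], gt$y1[ks], gt$x2[ks],
                                       gt$y2[ks])
    }
    list(tgt = tgt, pos = if (length(pos)) do.call(rbind, pos)
                          else matrix(0, 0, 7))
  })
}

# gather positive cells of a (H, W, 4, N) map into a (P, 4) matrix
ag_gather_cells <- function(x, pos) {
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]
  P <- nrow(pos)
  idx <- matrix(0L, P, C)
  for (c in seq_len(C))
    idx[, c] <- pos[, 1] + H * ((pos[, 2] - 1L) + W * ((c - 1L) +
                C * (pos[, 3] - 1L)))
  ag_op(matrix(x$v[as.vector(idx)], P, C), list(x), function(g) {
    dx <- array(0, dim = d)
    for (c in seq_len(C)) {
      acc <- tapply(g[, c], idx[, c], sum)
      dx[as.integer(names(acc))] <- dx[as.integer(names(acc))] + acc
    }
    list(dx)
  })
}

# CIoU between predicted (P, 4) autograd boxes and fixed ground-truth boxes
ag_ciou <- function(pred, gt, eps = 1e-9) {
  g1 <- ag_const(gt[, 1]); g2 <- ag_const(gt[, 2])
  g3 <- ag_const(gt[, 3]); g4 <- ag_const(gt[, 4])
  p1 <- ag_cols(pred, 1); p2 <- ag_cols(pred, 2)
  p3 <- ag_cols(pred, 3); p4 <- ag_cols(pred, 4)
  dimv <- function(x) ag_reshape(x, nrow(gt))
  p1 <- dimv(p1); p2 <- dimv(p2); p3 <- dimv(p3); p4 <- dimv(p4)
  iw <- ag_relu(ag_sub(ag_min2(p3, g3), ag_max2(p1, g1)))
  ih <- ag_relu(ag_sub(ag_min2(p4, g4), ag_max2(p2, g2)))
  inter <- ag_mul(iw, ih)
  ap <- ag_mul(ag_relu(ag_sub(p3, p1)), ag_relu(ag_sub(p4, p2)))
  ag_area <- (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2])
  un <- ag_add(ag_sub(ag_add(ap, ag_const(ag_area)), inter),
               ag_const(rep(eps, nrow(gt))))
  iou <- ag_div(inter, un)
  # center distance over enclosing-box diagonal
  pcx <- ag_scale(ag_add(p1, p3), 0.5); pcy <- ag_scale(ag_add(p2, p4), 0.5)
  gcx <- (gt[, 1] + gt[, 3]) / 2; gcy <- (gt[, 2] + gt[, 4]) / 2
  rho2 <- ag_add(ag_square(ag_sub(pcx, ag_const(gcx))),
                 ag_square(ag_sub(pcy, ag_const(gcy))))
  ex1 <- ag_min2(p1, g1); ey1 <- ag_min2(p2, g2)
  ex2 <- ag_max2(p3, g3); ey2 <- ag_max2(p4, g4)
  c2 <- ag_add(ag_add(ag_square(ag_sub(ex2, ex1)),
                      ag_square(ag_sub(ey2, ey1))),
               ag_const(rep(eps, nrow(gt))))
  # aspect-ratio term; alpha is treated as a constant, as is standard
  wg <- gt[, 3] - gt[, 1]; hg <- pmax(gt[, 4] - gt[, 2], eps)
  pw <- ag_relu(ag_sub(p3, p1)); ph0 <- ag_max2(ag_relu(ag_sub(p4, p2)),
                                                rep(eps, nrow(gt)))
  v <- ag_scale(ag_square(ag_sub(ag_const(atan(wg / hg)),
                                 ag_atan(ag_div(pw, ph0)))), 4 / pi^2)
  alpha <- v$v / (1 - iou$v + v$v + eps)
  ag_sub(iou, ag_add(ag_div(rho2, c2), ag_mul(ag_const(alpha), v)))
}

# total detection loss; raw from head forward, targets in pixels
detection_loss <- function(raw, targets, cls_weight = 1, box_weight = 5,
                           radius = 2.5) {
  asg <- assign_targets(raw, targets, radius)
  npos <- sum(vapply(asg, function(a) nrow(a$pos), numeric(1)))
  n_entries <- sum(vapply(raw, function(lv) length(lv$cls$v), numeric(1)))
  norm <- if (npos > 0) npos else n_entries
  cls_terms <- list(); box_terms <- list()
  for (k in seq_along(raw)) {
    lv <- raw[[k]]
    bce <- ag_sub(ag_softplus(lv$cls),
                  ag_mul(lv$cls, ag_const(asg[[k]]$tgt)))
    cls_terms[[k]] <- ag_sum(bce)
    pos <- asg[[k]]$pos
    if (nrow(pos) > 0L) {
      s <- lv$stride
      ltrb <- ag_gather_cells(lv$box, pos)       # (P, 4), stride units
      cxs <- (pos[, 2] - 0.5) * s; cys <- (pos[, 1] - 0.5) * s
      l <- ag_reshape(ag_cols(ltrb, 1), nrow(pos))
      t <- ag_reshape(ag_cols(ltrb, 2), nrow(pos))
      r <- ag_reshape(ag_cols(ltrb, 3), nrow(pos))
      b <- ag_reshape(ag_cols(ltrb, 4), nrow(pos))
      pred <- ag_cbind(list(
        ag_reshape(ag_sub(ag_const(cxs), ag_scale(l, s)), c(nrow(pos), 1)),
        ag_reshape(ag_sub(ag_const(cys), ag_scale(t, s)), c(nrow(pos), 1)),
        ag_reshape(ag_add(ag_const(cxs), ag_scale(r, s)), c(nrow(pos), 1)),
        ag_reshape(ag_add(ag_const(cys), ag_scale(b, s)), c(nrow(pos), 1))))
      ciou <- ag_ciou(pred, pos[, 4:7, drop = FALSE])
      box_terms[[length(box_terms) + 1L]] <-
        ag_sum(ag_sub(ag_const(rep(1, nrow(pos))), ciou))
    }
  }
  cls_loss <- ag_scale(Reduce(ag_add, cls_terms), 1 / norm)
  box_loss <- if (length(box_terms))
    ag_scale(Reduce(ag_add, box_terms), 1 / norm) else ag_const(0)
  total <- ag_add(ag_scale(cls_loss, cls_weight),
                  ag_scale(box_loss, box_weight))
  list(total = total, cls = cls_loss$v, box = box_loss$v, n_pos = npos)
}
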