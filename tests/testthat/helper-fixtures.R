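# Shared fixtures and independent oracles for the test suite.

ns_ <- asNamespace("alpdnet")

# random box set on a [0, size]^2 canvas
random_boxes <- function(n, size = 100, seed = NULL, classes = 0L) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L)
    return(data.frame(image = integer(), class_id = integer(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  x1 <- runif(n, 0, size * 0.7); y1 <- runif(n, 0, size * 0.7)
  data.frame(image = 1L,
             class_id = sample(classes, n, replace = TRUE),
             x1 = x1, y1 = y1,
             x2 = x1 + runif(n, size * 0.1, size * 0.3),
             y2 = y1 + runif(n, size * 0.1, size * 0.3))
}

# Independent brute-force AP oracle: evaluates (P, R) at every score cut
# with its own O(n^2) matcher, then integrates the precision envelope on
# the explicit recall grid. Shares no code with the package implementation.
brute_force_ap <- function(dets, gts, iou_thresh = 0.5) {
  if (nrow(gts) == 0L) return(NA_real_)
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
      inter
    if (ua <= 0) 0 else inter / ua
  }
  cuts <- sort(unique(dets$score), decreasing = TRUE)
  pts <- data.frame(recall = 0, precision = 1)
  for (th in cuts) {
    keep <- dets[dets$score >= th, , drop = FALSE]
    keep <- keep[order(-keep$score), , drop = FALSE]
    used <- rep(FALSE, nrow(gts))
    tp <- 0L
    for (i in seq_len(nrow(keep))) {
      best <- 0; bj <- 0L
      for (j in seq_len(nrow(gts))) {
        if (used[j] || gts$image[j] != keep$image[i]) next
        v <- iou1(as.numeric(keep[i, c("x1", "y1", "x2", "y2")]),
                  as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0L && best >= iou_thresh) { tp <- tp + 1L; used[bj] <- TRUE }
    }
    pts <- rbind(pts, data.frame(recall = tp / nrow(gts),
                                 precision = tp / nrow(keep)))
  }
  rec <- sort(unique(pts$recall))
  ap <- 0
  prev <- 0
  for (r in rec) {
    if (r == 0) next
    p_int <- max(pts$precision[pts$recall >= r])
    ap <- ap + (r - prev) * p_int
    prev <- r
  }
  ap
}

# tiny reduced-width configuration for model-level tests
tiny_cfg <- function(preset = "alpd-net", image_size = 64L) {
  alpd_config(preset, image_size = image_size,
              widths = c(8L, 16L, 32L, 64L),
              head = list(branch_width = c(8L, 8L, 8L)),
              pffm = list(heads = 4L, kv_tokens = 64L))
}

small_scene_spec <- function(size = 96L, seed = 0L, ...) {
  scene_spec(image_size = size, plant_radius = c(8, size * 0.3),
             seed = seed, ...)
}
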