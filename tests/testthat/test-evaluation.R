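test_that("greedy matching counts TP/FP/FN with one-to-one ownership", {
  gt <- data.frame(image = 1L, class_id = 0L, x1 = 0, y1 = 0,
                   x2 = 10, y2 = 10)
  det <- data.frame(image = 1L, class_id = 0L, score = 0.9,
                    x1 = 1, y1 = 0, x2 = 10, y2 = 10)  # IoU 0.9
  cnt <- match_detections(det, gt, 0.5)
  expect_equal(cnt$tp, 1); expect_equal(cnt$fp, 0); expect_equal(cnt$fn, 0)

  det2 <- rbind(det, transform(det, score = 0.7))
  cnt2 <- match_detections(det2, gt, 0.5)
  expect_equal(cnt2$tp, 1); expect_equal(cnt2$fp, 1)

  det3 <- transform(det, class_id = 1L)
  cnt3 <- match_detections(det3, gt, 0.5)
  expect_equal(sum(cnt3$tp), 0)
  expect_equal(sum(cnt3$fp), 1)
  expect_equal(sum(cnt3$fn), 1)
})

test_that("precision/recall formulas and zero-denominator conventions", {
  expect_equal(unname(precision_recall(
    data.frame(tp = 3, fp = 1, fn = 0))["precision"]), 0.75)
  expect_equal(unname(precision_recall(
    data.frame(tp = 3, fp = 0, fn = 1))["recall"]), 0.75)
  pr <- precision_recall(data.frame(tp = 0, fp = 0, fn = 2))
  expect_equal(unname(pr["precision"]), 1)  # no predictions
  pr2 <- precision_recall(data.frame(tp = 0, fp = 3, fn = 0))
  expect_equal(unname(pr2["recall"]), 0)    # no ground truths
})

test_that("hand-computed AP cases", {
  gt <- data.frame(image = 1L, class_id = 0L, x1 = 0, y1 = 0,
                   x2 = 10, y2 = 10)
  # detected first try at high score -> AP 1
  det <- data.frame(image = 1L, class_id = 0L, score = 0.95,
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  expect_equal(ap_from_curve(pr_curve(det, gt)), 1)
  # FP at 0.9 then TP at 0.8: envelope precision at recall 1 is 0.5
  det2 <- data.frame(image = 1L, class_id = 0L, score = c(0.9, 0.8),
                     x1 = c(50, 0), y1 = c(50, 0),
                     x2 = c(60, 10), y2 = c(60, 10))
  expect_equal(ap_from_curve(pr_curve(det2, gt)), 0.5)
})

test_that("AP equals the brute-force oracle on random small instances", {
  set.seed(20)
  for (case in 1:200) {
    n_gt <- sample(1:8, 1); n_det <- sample(0:8, 1)
    gt <- random_boxes(n_gt, seed = NULL)
    det <- random_boxes(n_det)
    if (n_det > 0) {
      det$score <- runif(n_det)
      # let some detections coincide with ground truths so TPs exist
      k <- min(n_det, n_gt)
      if (k > 0 && runif(1) < 0.8) {
        jit <- matrix(runif(k * 4, -2, 2), k)
        det[1:k, c("x1", "y1", "x2", "y2")] <-
          gt[1:k, c("x1", "y1", "x2", "y2")] + jit
      }
    } else det$score <- numeric(0)
    ap_pkg <- ap_from_curve(pr_curve(det, gt, 0.5))
    ap_bf <- brute_force_ap(det, gt, 0.5)
    expect_equal(ap_pkg, ap_bf, tolerance = 1e-9,
                 label = sprintf("case %d", case))
  }
})

test_that("adding a top-scored true positive never decreases AP", {
  set.seed(5)
  for (case in 1:20) {
    gt <- random_boxes(sample(2:6, 1))
    det <- random_boxes(sample(1:6, 1))
    det$score <- runif(nrow(det))
    ap0 <- ap_from_curve(pr_curve(det, gt))
    extra <- gt[sample(nrow(gt), 1), ]
    extra$score <- 1
    det2 <- rbind(det, extra[, names(det)])
    ap1 <- ap_from_curve(pr_curve(det2, gt))
    expect_gte(ap1 + 1e-12, ap0)
  }
})

test_that("mAP averages per-class APs and skips absent classes", {
  gt <- rbind(
    data.frame(image = 1L, class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10),
    data.frame(image = 1L, class_id = 1L, x1 = 30, y1 = 30, x2 = 45,
               y2 = 45))
  det <- rbind(
    data.frame(image = 1L, class_id = 0L, score = 0.9, x1 = 0, y1 = 0,
               x2 = 10, y2 = 10),
    data.frame(image = 1L, class_id = 1L, score = 0.8, x1 = 100, y1 = 100,
               x2 = 110, y2 = 110))
  m <- map50(det, gt, n_classes = 3L)
  expect_equal(m$per_class$ap, c(1, 0, NA_real_))
  expect_equal(m$map, 0.5)   # class 2 has no ground truth, excluded
  # identical APs across thresholds average to themselves
  m95 <- map50_95(det[1, ], gt[1, ], n_classes = 3L)
  expect_equal(m95$map, 1)
})

test_that("F1-confidence curve matches hand computation on a toy set", {
  gt <- rbind(
    data.frame(image = 1L, class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10),
    data.frame(image = 1L, class_id = 0L, x1 = 20, y1 = 20, x2 = 30,
               y2 = 30),
    data.frame(image = 1L, class_id = 1L, x1 = 50, y1 = 50, x2 = 60,
               y2 = 60))
  det <- rbind(
    data.frame(image = 1L, class_id = 0L, score = 0.9, x1 = 0, y1 = 0,
               x2 = 10, y2 = 10),                       # TP
    data.frame(image = 1L, class_id = 0L, score = 0.4, x1 = 70, y1 = 70,
               x2 = 80, y2 = 80),                       # FP (low score)
    data.frame(image = 1L, class_id = 1L, score = 0.8, x1 = 50, y1 = 50,
               x2 = 60, y2 = 60))                       # TP
  fc <- f1_confidence_curve(det, gt, grid = c(0.3, 0.6),
                            n_classes = 2L)
  # at 0.6: class0 P=1 R=1/2 F1=2/3; class1 P=1 R=1 F1=1 -> macro 5/6
  expect_equal(fc$curve$f1[fc$curve$threshold == 0.6], mean(c(2 / 3, 1)))
  # at 0.3: class0 P=1/2 R=1/2 F1=1/2; class1 F1=1 -> macro 3/4
  expect_equal(fc$curve$f1[fc$curve$threshold == 0.3], 0.75)
  expect_equal(fc$best_threshold, 0.6)

  # perfect detector: F1 = 1 below the minimum score
  fcp <- f1_confidence_curve(det[c(1, 3), ], gt[c(1, 3), ],
                             grid = c(0.5), n_classes = 2L)
  expect_equal(fcp$best_f1, 1)
  # no detections: F1 = 0 everywhere
  fc0 <- f1_confidence_curve(det[0, ], gt, grid = c(0.2, 0.5),
                             n_classes = 2L)
  expect_equal(fc0$curve$f1, c(0, 0))
})

test_that("diagnostic plot files are written", {
  gt <- random_boxes(4, seed = 2, classes = 0:2)
  det <- transform(gt, score = runif(4))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_pr_curves(det, gt, f1)
  plot_f1_curve(det, gt, f2)
  expect_true(file.size(f1) > 0)
  expect_true(file.size(f2) > 0)
})
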