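test_that("YOLO label files round-trip and reject malformed input", {
  lab <- data.frame(class_id = c(0L, 1L, 2L),
                    cx = c(0.5, 0.25, 0.8), cy = c(0.5, 0.3, 0.6),
                    w = c(0.2, 0.1, 0.05), h = c(0.1, 0.2, 0.12))
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(lab, f)
  back <- read_yolo_labels(f)
  expect_equal(back, lab, tolerance = 1e-6)

  writeLines(character(), f)
  expect_equal(nrow(read_yolo_labels(f)), 0L)

  writeLines("0 0.5 0.5 0.2 0.1", f)
  expect_equal(read_yolo_labels(f),
               data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                          w = 0.2, h = 0.1))

  writeLines(c("0 0.5 0.5 0.2 0.1", "1 0.2 0.3"), f)
  expect_error(read_yolo_labels(f), "line 2")
  writeLines("7 0.5 0.5 0.2 0.1", f)
  expect_error(read_yolo_labels(f), "class id")
  writeLines("0 1.5 0.5 0.2 0.1", f)
  expect_error(read_yolo_labels(f), "out of bounds")
})

test_that("tile grid matches ceiling arithmetic for full-size UAV frames", {
  g <- tile_grid_dims(8192, 5460, 640)
  expect_equal(unname(g["cols"]), 13L)
  expect_equal(unname(g["rows"]), 9L)
  expect_equal(unname(g["tiles"]), 117L)
})

test_that("tiling clips, keeps and re-normalizes boxes correctly", {
  img <- array(runif(100 * 160 * 3), c(100, 160, 3))
  # box fully inside the first 80x80 tile
  lab <- data.frame(class_id = 0L, cx = 20 / 160, cy = 30 / 100,
                    w = 20 / 160, h = 20 / 100)
  tiles <- tile_image(img, lab, tile_size = 80, min_area_frac = 0.3)
  expect_length(tiles, 2 * 2)
  n_boxes <- vapply(tiles, function(t) nrow(t$labels), numeric(1))
  expect_equal(sum(n_boxes), 1)
  t1 <- tiles[[which(n_boxes == 1)]]
  expect_equal(t1$row, 1); expect_equal(t1$col, 1)
  expect_equal(t1$labels$w * 80, 20, tolerance = 1e-9)
  expect_equal(t1$labels$cx * 80, 20, tolerance = 1e-9)

  # box straddling two tiles with a 0.25/0.75 area split
  lab2 <- data.frame(class_id = 1L, cx = 85 / 160, cy = 0.3,
                     w = 40 / 160, h = 0.2)
  # x-range 65..105; tile boundary at 80 -> left share 15/40, right 25/40
  tiles2 <- tile_image(img, lab2, tile_size = 80, min_area_frac = 0.5)
  kept <- which(vapply(tiles2, function(t) nrow(t$labels), numeric(1)) > 0)
  expect_length(kept, 1L)
  expect_equal(tiles2[[kept]]$col, 2L)  # only the 62.5%-area side survives

  # remainder tiles are zero-padded to full size
  expect_identical(dim(tiles2[[4]]$image), c(80L, 80L, 3L))
})

test_that("tiling conserves labeled area when nothing is dropped", {
  img <- array(0, c(64, 64, 3))
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  tiles <- tile_image(img, lab, tile_size = 32, min_area_frac = 0)
  areas <- vapply(tiles, function(t)
    if (nrow(t$labels)) sum(t$labels$w * 32 * t$labels$h * 32) else 0,
    numeric(1))
  expect_equal(sum(areas), (0.5 * 64)^2, tolerance = 1e-9)
})

test_that("split matches the published 8:1:1 arithmetic and is seeded", {
  sm <- split_dataset(seq_len(10260), seed = 1)
  counts <- table(sm$assignment$split)
  expect_equal(unname(counts["train"]), 8208)
  expect_equal(unname(counts["val"]), 1026)
  expect_equal(unname(counts["test"]), 1026)

  sm10 <- split_dataset(1:10, seed = 1)
  c10 <- table(sm10$assignment$split)
  expect_equal(unname(c10["train"]), 8)
  expect_equal(unname(c10["val"]), 1)
  expect_equal(unname(c10["test"]), 1)

  sm2 <- split_dataset(seq_len(10260), seed = 1)
  expect_identical(sm$assignment, sm2$assignment)
  sm3 <- split_dataset(seq_len(10260), seed = 2)
  expect_false(identical(sm$assignment, sm3$assignment))
})

test_that("split is a partition and stratification holds per class", {
  ids <- seq_len(600)
  cls <- rep(0:2, each = 200)
  sm <- split_dataset(ids, seed = 4, class_of = cls)
  expect_setequal(sm$assignment$id, ids)
  expect_false(anyDuplicated(sm$assignment$id) > 0)
  for (cl in 0:2) {
    sub <- sm$assignment[sm$assignment$class == cl, ]
    expect_equal(sum(sub$split == "val"), 20)
    expect_equal(sum(sub$split == "test"), 20)
    expect_equal(sum(sub$split == "train"), 160)
  }
  expect_error(split_dataset(integer()), "no records")
  expect_error(split_dataset(1:10, ratios = c(0.5, 0.2, 0.2)), "ratios")
})

test_that("mirror and rotation transform boxes by the exact identities", {
  img <- array(as.integer(round(runif(40 * 40 * 3) * 255)), c(40, 40, 3))
  lab <- data.frame(class_id = 0L, cx = 0.3, cy = 0.6, w = 0.2, h = 0.1)
  m <- augment_record(list(image = img, labels = lab), "mirror")
  expect_equal(m$labels$cx, 0.7)
  expect_equal(m$labels[, c("cy", "w", "h")], lab[, c("cy", "w", "h")])
  expect_identical(m$image[, , 1], img[, 40:1, 1])

  # a single clockwise quarter turn: (cx, cy, w, h) -> (1 - cy, cx, h, w)
  r <- ns_$rot90cw(img, 1)
  lr <- data.frame(class_id = lab$class_id, cx = 1 - lab$cy, cy = lab$cx,
                   w = lab$h, h = lab$w)
  # pixel at (row y, col x) moves to (row x, col H - y + 1)
  expect_equal(r[5, 40 - 7 + 1, 2], img[7, 5, 2])
  expect_equal(dim(r), dim(img))
  # box identity is what augment_record applies once per sampled turn
  a <- augment_record(list(image = img, labels = lab), "rotate",
                      rng_seed = 1)
  expect_true(nrow(a$labels) == 1)
  expect_equal(a$labels$w * a$labels$h, lab$w * lab$h, tolerance = 1e-12)
})

test_that("brightness scales pixels and leaves labels untouched", {
  img <- array(100, c(16, 16, 3))
  lab <- data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.4, h = 0.4)
  a <- augment_record(list(image = img, labels = lab), "brightness",
                      rng_seed = 3, brightness_range = c(1.3, 1.3))
  expect_equal(mean(a$image), 130, tolerance = 0.5)
  expect_equal(a$labels, lab)
  # clipping at 255
  img2 <- array(220, c(8, 8, 3))
  a2 <- augment_record(list(image = img2, labels = lab), "brightness",
                       rng_seed = 3, brightness_range = c(1.3, 1.3))
  expect_true(all(a2$image <= 255))
})

test_that("translation shifts boxes with the image and drops clipped ones", {
  img <- array(0, c(50, 50, 3))
  img[20:30, 20:30, 2] <- 200
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.22, h = 0.22)
  a <- augment_record(list(image = img, labels = lab), "translate",
                      rng_seed = 8, translate_frac = 0.2)
  if (nrow(a$labels)) {
    # the bright patch must still sit inside the shifted box
    S <- 50
    x1 <- max(1, floor((a$labels$cx - a$labels$w / 2) * S))
    x2 <- min(S, ceiling((a$labels$cx + a$labels$w / 2) * S))
    y1 <- max(1, floor((a$labels$cy - a$labels$h / 2) * S))
    y2 <- min(S, ceiling((a$labels$cy + a$labels$h / 2) * S))
    expect_gt(max(a$image[y1:y2, x1:x2, 2]), 100)
  }
  expect_error(augment_record(list(image = img, labels = lab), "warp"),
               "unknown")
})

test_that("expand_dataset yields 5x records and preserves split tags", {
  img <- array(as.integer(round(runif(24 * 24 * 3) * 255)), c(24, 24, 3))
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.3, h = 0.3)
  records <- lapply(1:6, function(i)
    list(image = img, labels = lab,
         split = c("train", "val", "test")[1 + (i %% 3)]))
  out <- expand_dataset(records, seed = 1)
  expect_length(out, 30L)
  for (o in out) {
    src <- records[[o$origin]]
    expect_identical(o$split, src$split)  # no leakage across splits
  }
  # restriction to train only
  out2 <- expand_dataset(records, seed = 1, splits = "train")
  n_train <- sum(vapply(records, function(r) r$split == "train", logical(1)))
  expect_length(out2, length(records) + 4L * n_train)
})

test_that("augmented scenes keep plant pixels inside transformed boxes", {
  sp <- small_scene_spec(size = 80, seed = 13, weed_density = 1,
                         occlusion_prob = 0)
  sc <- generate_scene(sp, 2)
  rec <- list(image = sc$image, labels = sc$labels)
  for (op in c("mirror", "rotate", "translate")) {
    a <- augment_record(rec, op, rng_seed = 5)
    lab <- a$labels
    for (k in seq_len(nrow(lab))) {
      S <- dim(a$image)[1]
      x1 <- max(1, floor((lab$cx[k] - lab$w[k] / 2) * S))
      x2 <- min(S, ceiling((lab$cx[k] + lab$w[k] / 2) * S))
      y1 <- max(1, floor((lab$cy[k] - lab$h[k] / 2) * S))
      y2 <- min(S, ceiling((lab$cy[k] + lab$h[k] / 2) * S))
      patch <- a$image[y1:y2, x1:x2, , drop = FALSE]
      expect_gt(mean(patch[, , 2] > patch[, , 1]), 0.1,
                label = sprintf("op %s box %d", op, k))
    }
  }
})
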