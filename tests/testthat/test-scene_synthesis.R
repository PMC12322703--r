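test_that("scene generation is a deterministic function of (seed, index)", {
  sp <- small_scene_spec(size = 96, seed = 11)
  s1 <- generate_scene(sp, 4)
  s2 <- generate_scene(sp, 4)
  expect_identical(s1, s2)
  s3 <- generate_scene(sp, 5)
  expect_false(identical(s1$image, s3$image))
  # determinism must hold regardless of ambient RNG state
  set.seed(999); runif(10)
  s4 <- generate_scene(sp, 4)
  expect_identical(s1, s4)
})

test_that("scene labels respect the spec contracts", {
  sp <- small_scene_spec(size = 96, seed = 2)
  for (i in 1:5) {
    sc <- generate_scene(sp, i)
    expect_identical(dim(sc$image), c(96L, 96L, 3L))
    expect_true(all(sc$image >= 0L & sc$image <= 255L))
    lab <- sc$labels
    if (nrow(lab) == 0L) next
    expect_true(all(lab$class_id %in% 0:2))
    expect_true(all(lab$cx - lab$w / 2 >= -1e-9))
    expect_true(all(lab$cx + lab$w / 2 <= 1 + 1e-9))
    expect_true(all(lab$cy - lab$h / 2 >= -1e-9))
    expect_true(all(lab$cy + lab$h / 2 <= 1 + 1e-9))
  }
})

test_that("zero plants per image yields no labels", {
  sp <- scene_spec(image_size = 64, plants_per_image = c(0L, 0L),
                   plant_radius = c(8, 16), seed = 1)
  sc <- generate_scene(sp, 1)
  expect_equal(nrow(sc$labels), 0L)
})

test_that("without occlusion every rendered plant is labeled", {
  sp <- scene_spec(image_size = 128, plants_per_image = c(5L, 5L),
                   plant_radius = c(10, 16), weed_density = 0,
                   occlusion_prob = 0, seed = 42)
  # plants may still shade each other; accept >= 1 label and exactly 5
  # whenever mutual overlap stays below the visibility threshold
  counts <- vapply(1:8, function(i) nrow(generate_scene(sp, i)$labels),
                   numeric(1))
  expect_true(all(counts >= 1 & counts <= 5))
  expect_true(any(counts == 5))
})

test_that("labeled boxes contain plant-colored pixels", {
  sp <- small_scene_spec(size = 96, seed = 7, weed_density = 2)
  for (i in 1:4) {
    sc <- generate_scene(sp, i)
    lab <- sc$labels
    for (k in seq_len(nrow(lab))) {
      S <- 96
      x1 <- max(1, floor((lab$cx[k] - lab$w[k] / 2) * S))
      x2 <- min(S, ceiling((lab$cx[k] + lab$w[k] / 2) * S))
      y1 <- max(1, floor((lab$cy[k] - lab$h[k] / 2) * S))
      y2 <- min(S, ceiling((lab$cy[k] + lab$h[k] / 2) * S))
      patch <- sc$image[y1:y2, x1:x2, , drop = FALSE]
      # vegetation is green-dominant; soil background is red-dominant
      expect_gt(mean(patch[, , 2] > patch[, , 1]), 0.1)
    }
  }
})

test_that("class-conditional appearance differs between classes", {
  sp <- scene_spec(image_size = 96, plants_per_image = c(1L, 1L),
                   plant_radius = c(20, 25), weed_density = 0,
                   occlusion_prob = 0, seed = 5)
  # gather mean green/red ratio inside the single label, per class
  ratios <- list("0" = c(), "1" = c(), "2" = c())
  for (i in 1:30) {
    sc <- generate_scene(sp, i)
    if (nrow(sc$labels) != 1L) next
    lab <- sc$labels[1, ]
    S <- 96
    x1 <- max(1, floor((lab$cx - lab$w / 2) * S))
    x2 <- min(S, ceiling((lab$cx + lab$w / 2) * S))
    y1 <- max(1, floor((lab$cy - lab$h / 2) * S))
    y2 <- min(S, ceiling((lab$cy + lab$h / 2) * S))
    patch <- sc$image[y1:y2, x1:x2, , drop = FALSE]
    key <- as.character(lab$class_id)
    ratios[[key]] <- c(ratios[[key]],
                       mean(patch[, , 3]) / mean(patch[, , 2]))
  }
  ms <- vapply(ratios, mean, numeric(1))
  expect_true(max(ms) - min(ms) > 0.005)  # hue bands are distinguishable
})

test_that("generate_dataset writes reproducible files and a manifest", {
  sp <- small_scene_spec(size = 64, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  mf1 <- generate_dataset(sp, 6, d1)
  mf2 <- generate_dataset(sp, 6, d2)
  expect_equal(nrow(mf1), 6L)
  expect_true(all(file.exists(file.path(d1, mf1$image))))
  expect_true(all(file.exists(file.path(d1, mf1$labels))))
  expect_true(file.exists(file.path(d1, "manifest.txt")))
  for (i in 1:6) {
    expect_identical(readBin(file.path(d1, mf1$image[i]), "raw", 1e6),
                     readBin(file.path(d2, mf2$image[i]), "raw", 1e6))
    expect_identical(readLines(file.path(d1, mf1$labels[i])),
                     readLines(file.path(d2, mf2$labels[i])))
  }
})

test_that("per-class instance counts are balanced over many scenes", {
  sp <- scene_spec(image_size = 48, plants_per_image = c(2L, 4L),
                   plant_radius = c(6, 10), weed_density = 0,
                   occlusion_prob = 0, seed = 9)
  cls <- unlist(lapply(1:200, function(i)
    generate_scene(sp, i)$labels$class_id))
  counts <- table(factor(cls, levels = 0:2))
  expect_true(max(counts) <= 1.2 * mean(counts))
  expect_true(min(counts) >= 0.8 * mean(counts))
})

test_that("degenerate scene specs are rejected", {
  expect_error(scene_spec(image_size = 0), "image_size")
  expect_error(scene_spec(occlusion_prob = 1.5), "occlusion_prob")
  expect_error(scene_spec(plant_radius = c(10, 5)), "plant_radius")
})
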