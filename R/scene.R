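#' Synthetic UAV vegetation scenes
#'
#' Generates synthetic top-down vegetation scenes that emulate the
#' statistical structure of wild-licorice UAV tiles: three visually
#' similar plant classes rendered as rosettes of overlapping elliptical
#' leaves (each class has its own hue band, leaf count and leaf aspect
#' ratio), distractor "weed" blobs whose hues overlap the class bands,
#' partial occlusion, large within-class scale variation, and a
#' low-frequency mottled soil background with speckle. Every rendered
#' plant whose visible area fraction is at least 0.25 receives one
#' YOLO-format label; heavier occlusion leaves the plant unlabeled, the
#' same keep rule the tiler applies to clipped boxes.
#'
#' Scenes are a pure function of `(spec$seed, index)`, so any single
#' scene can be regenerated without replaying the dataset.
#'
#' @param image_size Scene side in pixels.
#' @param plants_per_image Integer range (length 2) of plants per scene.
#' @param plant_radius Pixel range of plant rosette radii (spans "small"
#'   to "large" targets).
#' @param weed_density Mean number of distractor weed blobs per scene.
#' @param occlusion_prob Probability that a plant is partially covered by
#'   an occluder blob.
#' @param brightness_jitter Half-width of the multiplicative brightness
#'   jitter applied to the whole scene.
#' @param seed Base seed of the scene stream.
#' @return `scene_spec` returns a validated specification object of class
#'   `"scene_spec"`.
#' @examples
#' sp <- scene_spec(image_size = 128, plant_radius = c(10, 30))
#' sc <- generate_scene(sp, 1)
#' dim(sc$image); sc$labels
#' @export
scene_spec <- function(image_size = 640L,
                       plants_per_image = c(2L, 6L),
                       plant_radius = c(12, 220),
                       weed_density = 8,
                       occlusion_prob = 0.3,
                       brightness_jitter = 0.15,
                       seed = 0L) {
  if (image_size < 16) stop("image_size too small to render scenes")
  if (length(plants_per_image) != 2L || any(plants_per_image < 0) ||
      plants_per_image[1] > plants_per_image[2])
    stop("plants_per_image must be a non-empty non-negative range")
  if (length(plant_radius) != 2L || any(plant_radius <= 0) ||
      plant_radius[1] > plant_radius[2])
    stop("plant_radius must be a positive range")
  if (occlusion_prob < 0 || occlusion_prob > 1)
    stop("occlusion_prob must lie in [0, 1]")
  if (weed_density < 0) stop("weed_density must be non-negative")
  structure(list(image_size = as.integer(image_size), n_classes = 3L,
                 plants_per_image = as.integer(plants_per_image),
                 plant_radius = plant_radius,
                 weed_density = weed_density,
                 occlusion_prob = occlusion_prob,
                 brightness_jitter = brightness_jitter,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# class appearance: hue band (base RGB), leaf count, leaf aspect
.class_looks <- list(
  list(rgb = c(0.35, 0.55, 0.16), leaves = 7L, aspect = 3.0),
  list(rgb = c(0.22, 0.50, 0.24), leaves = 10L, aspect = 2.2),
  list(rgb = c(0.42, 0.58, 0.28), leaves = 5L, aspect = 4.0))

# render one rotated-ellipse leaf into mask/image accumulators
render_leaf <- function(canvas, mask, cx, cy, len, wid, angle, col, jitter) {
  S <- nrow(canvas$r)
  ext <- ceiling(len) + 1L
  xs <- max(1L, floor(cx - ext)):min(S, ceiling(cx + ext))
  ys <- max(1L, floor(cy - ext)):min(S, ceiling(cy + ext))
  if (length(xs) == 0L || length(ys) == 0L) return(mask)
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  xr <- gx * cos(angle) + gy * sin(angle)
  yr <- -gx * sin(angle) + gy * cos(angle)
  # leaf grows outward from the rosette center: shift along major axis
  inside <- ((xr - len / 2)^2 / (len / 2)^2 + yr^2 / wid^2) <= 1
  if (!any(inside)) return(mask)
  idx <- which(inside, arr.ind = TRUE)
  rows <- ys[idx[, 1]]; cols <- xs[idx[, 2]]
  lin <- cbind(rows, cols)
  shade <- 1 - 0.25 * abs(yr[idx]) / wid
  chn <- c("r", "g", "b")
  for (ch in 1:3) {
    v <- pmin(1, pmax(0, col[ch] * shade * jitter))
    canvas[[chn[ch]]][lin] <- v
  }
  mask[lin] <- TRUE
  mask
}

render_rosette <- function(canvas, cx, cy, radius, look, rng_jit) {
  S <- nrow(canvas$r)
  mask <- matrix(FALSE, S, S)
  nl <- look$leaves
  base <- stats::runif(1, 0, 2 * pi)
  for (j in seq_len(nl)) {
    ang <- base + 2 * pi * (j - 1) / nl + stats::rnorm(1, 0, 0.12)
    len <- radius * stats::runif(1, 0.75, 1)
    wid <- len / look$aspect
    colj <- pmin(1, pmax(0, look$rgb + stats::rnorm(3, 0, 0.03)))
    mask <- render_leaf(canvas, mask, cx, cy, len, wid, ang, colj,
                        stats::runif(1, 0.85, 1.1))
  }
  mask
}

scene_background <- function(S) {
  g <- 8L
  coarse <- array(stats::runif(g * g * 3), c(g, g, 3, 1))
  base <- c(0.45, 0.38, 0.26)  # dry sandy soil
  for (ch in 1:3)
    coarse[, , ch, 1] <- base[ch] * (0.75 + 0.5 * coarse[, , ch, 1])
  sm <- array(cpp_resize_bilinear(as.numeric(coarse), g, g, 3L, 1L, S, S),
              c(S, S, 3))
  sm + array(stats::rnorm(S * S, 0, 0.025), c(S, S, 3))
}

#' Generate one synthetic scene
#'
#' @param spec A [scene_spec()].
#' @param index Scene index (deterministic key together with `spec$seed`).
#' @return A list of class `"scene_sample"`: `image` (integer array
#'   `(H, W, 3)`, values 0-255), `labels` (data.frame `class_id`, `cx`,
#'   `cy`, `w`, `h`, normalized center format).
#' @rdname scene_spec
#' @export
generate_scene <- function(spec, index) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed((spec$seed * 1000003L + as.integer(index)) %% 2147483647L)
  S <- spec$image_size
  bg <- scene_background(S)
  canvas <- new.env(parent = emptyenv())
  canvas$r <- bg[, , 1]; canvas$g <- bg[, , 2]; canvas$b <- bg[, , 3]
  np <- if (spec$plants_per_image[1] == spec$plants_per_image[2])
    spec$plants_per_image[1]
  else sample(spec$plants_per_image[1]:spec$plants_per_image[2], 1L)
  rmax <- min(spec$plant_radius[2], S * 0.45)
  rmin <- min(spec$plant_radius[1], rmax)
  plants <- list()
  if (np > 0) for (p in seq_len(np)) {
    radius <- stats::runif(1, rmin, rmax)
    cx <- stats::runif(1, radius * 0.6, S - radius * 0.6)
    cy <- stats::runif(1, radius * 0.6, S - radius * 0.6)
    cls <- sample(0:2, 1L)
    mask <- render_rosette(canvas, cx, cy, radius, .class_looks[[cls + 1L]],
                           NULL)
    plants[[p]] <- list(class_id = cls, mask_idx = which(mask),
                       cx = cx, cy = cy)
  }
  # weed blobs: hue overlapping the class bands (hard negatives)
  nw <- stats::rpois(1, spec$weed_density)
  weed_mask <- matrix(FALSE, S, S)
  if (nw > 0) for (k in seq_len(nw)) {
    wr <- stats::runif(1, rmin * 0.3, rmin * 1.2)
    wx <- stats::runif(1, 1, S); wy <- stats::runif(1, 1, S)
    look <- list(rgb = pmin(1, pmax(0, c(0.33, 0.52, 0.2) +
                                      stats::rnorm(3, 0, 0.05))),
                 leaves = sample(3:5, 1), aspect = stats::runif(1, 1.5, 3))
    weed_mask <- weed_mask | render_rosette(canvas, wx, wy, wr, look, NULL)
  }
  # occluders: extra blobs drawn over a plant with probability occlusion_prob
  for (p in plants) {
    if (stats::runif(1) < spec$occlusion_prob) {
      ext <- arrayInd(p$mask_idx, c(S, S))
      if (nrow(ext) == 0L) next
      pick <- ext[sample(nrow(ext), 1L), ]
      wr <- stats::runif(1, rmin * 0.5, rmin * 1.5)
      look <- list(rgb = pmin(1, pmax(0, c(0.3, 0.48, 0.22) +
                                        stats::rnorm(3, 0, 0.05))),
                   leaves = 6L, aspect = 2)
      weed_mask <- weed_mask |
        render_rosette(canvas, pick[2], pick[1], wr, look, NULL)
    }
  }
  img <- array(0, c(S, S, 3))
  img[, , 1] <- canvas$r; img[, , 2] <- canvas$g; img[, , 3] <- canvas$b
  bf <- stats::runif(1, 1 - spec$brightness_jitter,
                     1 + spec$brightness_jitter)
  img <- pmin(1, pmax(0, img * bf))
  # labels: box over the plant's rendered extent, kept when the visible
  # (non-occluded) fraction is at least 0.25
  labels <- list()
  covered <- matrix(FALSE, S, S)
  # plants rendered later sit on top of earlier ones
  for (p in rev(seq_along(plants))) {
    pm <- plants[[p]]$mask_idx
    plants[[p]]$occluded_by_plants <- sum(covered[pm])
    covered[pm] <- TRUE
  }
  for (p in plants) {
    pm <- p$mask_idx
    if (length(pm) == 0L) next
    occ <- sum(weed_mask[pm]) + p$occluded_by_plants
    vis_frac <- 1 - occ / length(pm)
    if (vis_frac < 0.25) next
    ext <- arrayInd(pm, c(S, S))
    y1 <- min(ext[, 1]) - 1L; y2 <- max(ext[, 1])
    x1 <- min(ext[, 2]) - 1L; x2 <- max(ext[, 2])
    labels[[length(labels) + 1L]] <- data.frame(
      class_id = p$class_id,
      cx = (x1 + x2) / 2 / S, cy = (y1 + y2) / 2 / S,
      w = (x2 - x1) / S, h = (y2 - y1) / S)
  }
  labels <- if (length(labels)) do.call(rbind, labels)
            else data.frame(class_id = integer(), cx = numeric(),
                            cy = numeric(), w = numeric(), h = numeric())
  list(image = array(as.integer(round(img * 255)), c(S, S, 3)),
       labels = labels) |>
    structure(class = "scene_sample")
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_images` scenes and writes PNG images, YOLO label files and a
#' manifest (one `image_path<TAB>label_path` pair per line). Re-running
#' with the same spec reproduces identical files.
#'
#' @param spec A [scene_spec()].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a data.frame manifest with columns `image` and
#'   `labels` (paths relative to `out_dir`).
#' @export
generate_dataset <- function(spec, n_images, out_dir) {
  stopifnot(inherits(spec, "scene_spec"), n_images >= 0)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(spec, i)
    ip <- file.path("images", sprintf("scene_%05d.png", i))
    lp <- file.path("labels", sprintf("scene_%05d.txt", i))
    ok <- try(png::writePNG(sc$image / 255, file.path(out_dir, ip)),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write image: ", file.path(out_dir, ip))
    write_yolo_labels(sc$labels, file.path(out_dir, lp))
    rows[[i]] <- data.frame(image = ip, labels = lp)
  }
  manifest <- if (n_images > 0) do.call(rbind, rows)
              else data.frame(image = character(), labels = character())
  utils::write.table(manifest, file.path(out_dir, "manifest.txt"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(manifest)
}

#' Read back a scene image as a numeric array in [0, 1]
#' @param path PNG path.
#' @return Numeric `(H, W, 3)` array.
#' @export
read_scene_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = TRUE]
}
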