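#' YOLO-format label I/O
#'
#' Labels are text files with one `"<class> <cx> <cy> <w> <h>"` line per
#' box, coordinates normalized to the image (center format, floats
#' written with 6 decimals). `read_yolo_labels` validates field counts,
#' class range and coordinate bounds and reports the offending line
#' number; an empty or missing-newline file yields zero rows.
#'
#' @param path Label file path.
#' @param n_classes Number of valid classes (ids `0:(n_classes-1)`).
#' @return A data.frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path, n_classes = 3L) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5L)
      stop(sprintf("parse error in %s line %d: expected 5 fields, got %d",
                   path, i, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("parse error in %s line %d: non-numeric field", path, i))
    cid <- as.integer(v[1])
    if (cid != v[1] || cid < 0L || cid >= n_classes)
      stop(sprintf("invalid class id %s in %s line %d", f[1], path, i))
    if (any(v[2:3] < 0 | v[2:3] > 1) || any(v[4:5] <= 0 | v[4:5] > 1))
      stop(sprintf("box out of bounds in %s line %d", path, i))
    data.frame(class_id = cid, cx = v[2], cy = v[3], w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' @param labels Data.frame of boxes as returned by `read_yolo_labels`.
#' @rdname read_yolo_labels
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- if (nrow(labels) == 0L) character() else
    sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$cx,
            labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

# normalized center boxes -> pixel xyxy (0-based, half-open)
yolo_to_xyxy <- function(labels, width, height) {
  data.frame(class_id = labels$class_id,
             x1 = (labels$cx - labels$w / 2) * width,
             y1 = (labels$cy - labels$h / 2) * height,
             x2 = (labels$cx + labels$w / 2) * width,
             y2 = (labels$cy + labels$h / 2) * height)
}

xyxy_to_yolo <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id,
             cx = (boxes$x1 + boxes$x2) / 2 / width,
             cy = (boxes$y1 + boxes$y2) / 2 / height,
             w = (boxes$x2 - boxes$x1) / width,
             h = (boxes$y2 - boxes$y1) / height)
}

#' Tile-grid dimensions for a frame
#'
#' @param width,height Frame size in pixels.
#' @param tile_size Tile side.
#' @return Named integer vector `c(rows =, cols =, tiles =)` (ceiling
#'   division; remainder tiles are padded).
#' @export
tile_grid_dims <- function(width, height, tile_size = 640L) {
  r <- as.integer(ceiling(height / tile_size))
  cc <- as.integer(ceiling(width / tile_size))
  c(rows = r, cols = cc, tiles = r * cc)
}

#' Tile a large frame into fixed-size tiles with box remapping
#'
#' Cuts a `(H, W, 3)` image into a non-overlapping grid of
#' `tile_size`-square tiles anchored at the top-left corner; remainder
#' tiles at the right/bottom are zero-padded. Every source box is clipped
#' to every tile it intersects and kept only when the clipped area is at
#' least `min_area_frac` of the original box area; kept boxes are
#' re-normalized to tile coordinates.
#'
#' @param image Numeric or integer `(H, W, 3)` array.
#' @param labels YOLO-format data.frame (normalized to the source frame).
#' @param tile_size Tile side in pixels.
#' @param min_area_frac Minimum clipped/original area ratio for keeping a
#'   box.
#' @return A list of tiles, each `list(image, labels, row, col)` with
#'   `labels` normalized to the tile.
#' @export
tile_image <- function(image, labels, tile_size = 640L,
                       min_area_frac = 0.3) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  stopifnot(tile_size > 0)
  g <- tile_grid_dims(W, H, tile_size)
  n_r <- g[["rows"]]; n_c <- g[["cols"]]
  px <- yolo_to_xyxy(labels, W, H)
  area0 <- pmax(0, px$x2 - px$x1) * pmax(0, px$y2 - px$y1)
  tiles <- list()
  for (r in seq_len(n_r)) for (cc in seq_len(n_c)) {
    y0 <- (r - 1L) * tile_size; x0 <- (cc - 1L) * tile_size
    th <- min(tile_size, H - y0); tw <- min(tile_size, W - x0)
    timg <- array(0, c(tile_size, tile_size, d[3]))
    timg[seq_len(th), seq_len(tw), ] <-
      image[y0 + seq_len(th), x0 + seq_len(tw), , drop = FALSE]
    cx1 <- pmax(px$x1, x0); cy1 <- pmax(px$y1, y0)
    cx2 <- pmin(px$x2, x0 + tile_size); cy2 <- pmin(px$y2, y0 + tile_size)
    carea <- pmax(0, cx2 - cx1) * pmax(0, cy2 - cy1)
    keep <- which(area0 > 0 & carea / pmax(area0, 1e-12) >= min_area_frac)
    tl <- if (length(keep)) {
      xyxy_to_yolo(data.frame(class_id = px$class_id[keep],
                              x1 = cx1[keep] - x0, y1 = cy1[keep] - y0,
                              x2 = cx2[keep] - x0, y2 = cy2[keep] - y0),
                   tile_size, tile_size)
    } else data.frame(class_id = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric())
    tiles[[length(tiles) + 1L]] <- list(image = timg, labels = tl,
                                        row = r, col = cc)
  }
  tiles
}

#' Split records into train/validation/test sets
#'
#' Deterministic seeded split. Validation and test receive
#' `round(n * ratio)` records each and the remainder goes to the training
#' set (so 10,260 records at 8:1:1 give 8,208/1,026/1,026). With
#' `stratify_by_class` the same rule is applied within each class of
#' `class_of`, keeping per-class ratios within one record of the global
#' ratios. Splitting precedes augmentation to avoid leakage.
#'
#' @param ids Character or integer record identifiers.
#' @param ratios Train/val/test fractions summing to 1.
#' @param seed Split seed.
#' @param class_of Optional per-record class used for stratification.
#' @param stratify_by_class Stratify when `class_of` is given.
#' @return An object of class `"split_manifest"`: list with `ratios`,
#'   `seed`, `assignment` (data.frame `id`, `class`, `split`) and
#'   `counts` (split x class table).
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 0L,
                          class_of = NULL, stratify_by_class = TRUE) {
  if (length(ids) == 0L) stop("no records to split")
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three positive fractions summing to 1")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  cls <- if (is.null(class_of)) rep(0L, length(ids)) else class_of
  stopifnot(length(cls) == length(ids))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  split <- character(length(ids))
  groups <- if (stratify_by_class && !is.null(class_of))
    split(seq_along(ids), cls) else list(seq_along(ids))
  for (g in groups) {
    n <- length(g)
    n_val <- round(n * ratios[2]); n_test <- round(n * ratios[3])
    n_val <- min(n_val, n); n_test <- min(n_test, n - n_val)
    ord <- g[sample.int(n)]
    split[ord[seq_len(n_val)]] <- "val"
    split[ord[n_val + seq_len(n_test)]] <- "test"
    split[ord[setdiff(seq_len(n), seq_len(n_val + n_test))]] <- "train"
  }
  assignment <- data.frame(id = ids, class = cls, split = split,
                           stringsAsFactors = FALSE)
  structure(list(ratios = ratios, seed = seed, assignment = assignment,
                 counts = table(assignment$split, assignment$class)),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("<split_manifest> seed", x$seed, "ratios",
      paste(x$ratios, collapse = ":"), "\n")
  print(table(x$assignment$split))
  invisible(x)
}

# rotate an (H, W, C) image 90 degrees clockwise k times
rot90cw <- function(img, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    d <- dim(img)
    out <- array(0, c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- t(img[d[1]:1, , ch])
    img <- out
  }
  img
}

#' Augment an image record
#'
#' The four label-aware augmentation operators: `mirror` (horizontal
#' flip; `cx -> 1 - cx`), `rotate` (a random multiple of 90 degrees, so
#' axis-aligned boxes stay tight; 90 degrees clockwise maps
#' `(cx, cy, w, h) -> (1 - cy, cx, h, w)`), `brightness` (multiplicative
#' factor drawn from `brightness_range`; labels untouched), and
#' `translate` (integer shift up to `translate_frac` of the image size
#' with zero fill; shifted boxes are clipped and dropped below
#' `min_area_frac`).
#'
#' @param record `list(image, labels)` with a `(H, W, 3)` image (0-255)
#'   and YOLO labels.
#' @param op One of `"mirror"`, `"rotate"`, `"brightness"`,
#'   `"translate"`.
#' @param rng_seed Seed for the operator's random draw.
#' @param min_area_frac Keep threshold for clipped boxes.
#' @param brightness_range,translate_frac Operator parameter ranges.
#' @return The augmented record (same structure).
#' @export
augment_record <- function(record, op, rng_seed = 0L, min_area_frac = 0.3,
                           brightness_range = c(0.6, 1.4),
                           translate_frac = 0.2) {
  stopifnot(is.array(record$image))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(rng_seed) %% 2147483647L)
  img <- record$image
  lab <- record$labels
  d <- dim(img)
  switch(op,
    mirror = {
      img <- img[, d[2]:1, , drop = FALSE]
      if (nrow(lab)) lab$cx <- 1 - lab$cx
    },
    rotate = {
      k <- sample(1:3, 1L)
      img <- rot90cw(img, k)
      if (nrow(lab)) for (i in seq_len(k)) {
        lab <- data.frame(class_id = lab$class_id, cx = 1 - lab$cy,
                          cy = lab$cx, w = lab$h, h = lab$w)
      }
    },
    brightness = {
      f <- stats::runif(1, brightness_range[1], brightness_range[2])
      img <- pmin(255, pmax(0, img * f))
      if (is.integer(record$image)) img <- array(as.integer(round(img)), d)
    },
    translate = {
      dx <- sample(-round(translate_frac * d[2]):round(translate_frac * d[2]), 1L)
      dy <- sample(-round(translate_frac * d[1]):round(translate_frac * d[1]), 1L)
      out <- array(0, d)
      src_r <- seq_len(d[1]) - dy; src_c <- seq_len(d[2]) - dx
      ok_r <- src_r >= 1 & src_r <= d[1]; ok_c <- src_c >= 1 & src_c <= d[2]
      out[which(ok_r), which(ok_c), ] <-
        img[src_r[ok_r], src_c[ok_c], , drop = FALSE]
      img <- out
      if (nrow(lab)) {
        px <- yolo_to_xyxy(lab, d[2], d[1])
        area0 <- (px$x2 - px$x1) * (px$y2 - px$y1)
        px$x1 <- px$x1 + dx; px$x2 <- px$x2 + dx
        px$y1 <- px$y1 + dy; px$y2 <- px$y2 + dy
        cx1 <- pmax(px$x1, 0); cy1 <- pmax(px$y1, 0)
        cx2 <- pmin(px$x2, d[2]); cy2 <- pmin(px$y2, d[1])
        carea <- pmax(0, cx2 - cx1) * pmax(0, cy2 - cy1)
        keep <- which(carea / pmax(area0, 1e-12) >= min_area_frac)
        lab <- if (length(keep))
          xyxy_to_yolo(data.frame(class_id = px$class_id[keep],
                                  x1 = cx1[keep], y1 = cy1[keep],
                                  x2 = cx2[keep], y2 = cy2[keep]),
                       d[2], d[1])
        else lab[0, ]
      }
    },
    stop("unknown augmentation op: ", op))
  list(image = img, labels = lab)
}

#' Expand a dataset with the four augmentation operators
#'
#' Each record yields itself plus one augmented copy per operator (5x by
#' default). Augmentation is applied within each split independently, so
#' split tags are preserved and no augmented copy crosses split
#' boundaries. Set `splits` to restrict augmentation (e.g. `"train"`
#' only, the recommended practice; the default augments every split to
#' mirror pipelines that report augmented counts for all three).
#'
#' @param records List of `list(image, labels, split)` records.
#' @param ops Operator names applied to each record.
#' @param seed Base seed; each (record, op) pair gets a derived seed.
#' @param splits Splits to augment (others pass through unexpanded).
#' @return The expanded record list; each element keeps its `split` and
#'   gains `origin` (source index) and `op` (`"orig"` or operator name).
#' @export
expand_dataset <- function(records,
                           ops = c("mirror", "rotate", "brightness",
                                   "translate"),
                           seed = 0L,
                           splits = c("train", "val", "test")) {
  out <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    rec$origin <- i; rec$op <- "orig"
    out[[length(out) + 1L]] <- rec
    if (!is.null(rec$split) && !(rec$split %in% splits)) next
    for (j in seq_along(ops)) {
      aug <- augment_record(list(image = rec$image, labels = rec$labels),
                            ops[j],
                            rng_seed = seed + i * 131L + j)
      aug$split <- rec$split
      aug$origin <- i; aug$op <- ops[j]
      out[[length(out) + 1L]] <- aug
    }
  }
  out
}
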