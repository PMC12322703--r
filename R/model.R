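#' Build a detector model
#'
#' Instantiates the full network described by an [alpd_config()]: the
#' ResNet-AL backbone (with ABSM/LMSM according to the ablation flags),
#' the progressive feature-fusion neck (when enabled) and the decoupled
#' detection head. Weights are randomly initialized (He-style for
#' convolutions) from the current RNG state; seed the session for
#' reproducible models.
#'
#' @param cfg An [alpd_config()] object or preset name.
#' @return An object of class `"alpd_model"` with the configuration and
#'   the parameterized modules.
#' @examples
#' set.seed(1)
#' m <- alpd_model(alpd_config("resnet34-d", widths = c(8, 16, 32, 64),
#'                             head = list(branch_width = c(8, 8, 8))))
#' @export
alpd_model <- function(cfg) {
  if (is.character(cfg)) cfg <- alpd_config(cfg)
  stopifnot(inherits(cfg, "alpd_config"))
  mods <- list(backbone = backbone_new(cfg))
  if (cfg$enable_pffm) mods$pffm <- pffm_new(cfg)
  mods$head <- head_new(cfg)
  root <- new_module("alpd_net", children = mods)
  structure(list(cfg = cfg, net = root), class = "alpd_model")
}

#' @export
print.alpd_model <- function(x, ...) {
  cat("<alpd_model> preset:", x$cfg$preset, "\n")
  cat("  parameters:", format(n_params(x$net), big.mark = ","), "\n")
  print(x$cfg)
  invisible(x)
}

# forward pass on an image batch array (H, W, 3, N) scaled to [0, 1];
# returns the per-scale raw head maps
model_forward <- function(model, images, training = FALSE) {
  x <- if (is_ag(images)) images else ag_const(images)
  pyr <- model$net$children$backbone$forward(x, training)
  fused <- if (model$cfg$enable_pffm)
    model$net$children$pffm$forward(pyr, training)
  else list(A = pyr$a, B = pyr$b, C = pyr$c)
  model$net$children$head$forward(fused, training)
}

#' Run detection on images
#'
#' @param object An [alpd_model()].
#' @param images Numeric array `(H, W, 3, N)` (or `(H, W, 3)` for a single
#'   image) with values in `[0, 1]`.
#' @param conf_thresh,nms_iou Decoding thresholds.
#' @param ... Unused.
#' @return Detections as a data.frame (`image`, `class_id`, `score`,
#'   `x1`, `y1`, `x2`, `y2`), pixel xyxy coordinates.
#' @export
predict.alpd_model <- function(object, images, conf_thresh = 0.25,
                               nms_iou = 0.5, ...) {
  if (length(dim(images)) == 3L)
    images <- array(images, c(dim(images), 1L))
  raw <- model_forward(object, images, training = FALSE)
  decode_detections(raw, conf_thresh, nms_iou, img_size = dim(images)[1])
}

#' Profile a live forward pass and total its FLOPs
#'
#' Runs one forward pass of the instantiated network at the given input
#' size with layer tracing enabled, and returns the recorded per-layer
#' cost table. This is an independent cross-check of [count_flops()]: the
#' analytic accountant derives the table from the configuration alone,
#' while this profiler observes the layers the network actually executes.
#'
#' @param model An [alpd_model()].
#' @param input_size Input side in pixels (multiple of 32).
#' @return A list with `total_flops`, `total_gflops` and `table`.
#' @export
profile_model_flops <- function(model, input_size = 64L) {
  x <- array(stats::rnorm(input_size * input_size * 3),
             c(input_size, input_size, 3, 1))
  trace_start()
  on.exit(trace_stop(), add = TRUE)
  invisible(model_forward(model, x, training = FALSE))
  tab <- trace_stop()
  list(total_flops = sum(tab$flops), total_gflops = sum(tab$flops) / 1e9,
       table = tab)
}

#' Save / load model checkpoints
#'
#' A checkpoint holds the configuration, every weight array, and the
#' normalization running statistics.
#'
#' @param model An [alpd_model()].
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = module_state(model$net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- alpd_model(ck$cfg)
  load_module_state(model$net, ck$state)
  model
}
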