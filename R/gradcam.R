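#' Grad-CAM saliency maps
#'
#' Gradient-weighted class-activation mapping at a chosen backbone tap:
#' the class score (sum of the chosen class's logits over all prediction
#' cells) is back-propagated to the target activation; channel weights
#' are the spatially pooled gradients; the map is the ReLU of the
#' weighted channel sum, bilinearly upsampled to the input size and
#' min-max normalized to `[0, 1]`. If every gradient vanishes (the score
#' does not depend on the input), an all-zero map is returned.
#'
#' @param model An [alpd_model()].
#' @param image Numeric `(H, W, 3)` array in `[0, 1]`.
#' @param target_layer One of `"stage4"`, `"stage3"`, `"stage2"`
#'   (backbone taps at strides 32/16/8).
#' @param class_id Class of interest (0-based); defaults to the class
#'   with the largest total logit.
#' @return Numeric `(H, W)` matrix in `[0, 1]`.
#' @export
grad_cam <- function(model, image, target_layer = c("stage4", "stage3",
                                                    "stage2"),
                     class_id = NULL) {
  target_layer <- match.arg(target_layer)
  d <- dim(image)
  x <- ag_const(array(image, c(d[1], d[2], 3, 1)))
  pyr <- model$net$children$backbone$forward(x, training = FALSE)
  fused <- if (model$cfg$enable_pffm)
    model$net$children$pffm$forward(pyr, training = FALSE)
  else list(A = pyr$a, B = pyr$b, C = pyr$c)
  raw <- model$net$children$head$forward(fused, training = FALSE)
  if (is.null(class_id)) {
    tot <- sapply(seq_len(model$cfg$n_classes), function(cl)
      sum(vapply(raw, function(lv) sum(lv$cls$v[, , cl, ]), numeric(1))))
    class_id <- which.max(tot) - 1L
  }
  score <- Reduce(ag_add, lapply(raw, function(lv)
    ag_sum(ag_op(lv$cls$v[, , class_id + 1L, , drop = FALSE],
                 list(lv$cls), function(g) {
                   dc <- array(0, dim = dim(lv$cls$v))
                   dc[, , class_id + 1L, ] <- g
                   list(dc)
                 }))))
  target <- switch(target_layer, stage4 = pyr$a, stage3 = pyr$b,
                   stage2 = pyr$c)
  ag_backward(score)
  gr <- target$grad
  if (is.null(gr) || all(gr == 0)) return(matrix(0, d[1], d[2]))
  act <- target$v
  wts <- apply(gr, 3, mean)
  cam <- array(0, dim(act)[1:2])
  for (c in seq_along(wts)) cam <- cam + wts[c] * act[, , c, 1]
  cam <- pmax(cam, 0)
  up <- array(cpp_resize_bilinear(as.numeric(array(cam, c(dim(cam), 1, 1))),
                                  dim(cam)[1], dim(cam)[2], 1L, 1L,
                                  d[1], d[2]), c(d[1], d[2]))
  rng <- range(up)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, d[1], d[2]))
  (up - rng[1]) / (rng[2] - rng[1])
}

#' Write a Grad-CAM overlay PNG
#'
#' @param model,image,target_layer,class_id As in [grad_cam()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
grad_cam_overlay <- function(model, image, path,
                             target_layer = "stage4", class_id = NULL) {
  cam <- grad_cam(model, image, target_layer, class_id)
  over <- image
  over[, , 1] <- pmin(1, image[, , 1] * 0.5 + cam * 0.7)
  over[, , 2] <- image[, , 2] * 0.5
  over[, , 3] <- image[, , 3] * 0.5
  png::writePNG(over, path)
  invisible(path)
}
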