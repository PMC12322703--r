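#' Model configuration and ablation presets
#'
#' Builds the complete configuration of the detector: a ResNet34-style
#' backbone (stem, stages of BasicBlocks, per-stage widths), the adaptive
#' background-suppression module (ABSM) embedded in every BasicBlock, the
#' lightweight multi-scale module (LMSM) appended to every stage, the
#' progressive feature-fusion neck (PFFM) built from five weighted
#' self-attention fusion (WSAF) units, and the decoupled detection head.
#' The four ablation presets toggle ABSM / LMSM / PFFM so the ablation
#' chain \code{resnet34-d -> resnet34-ad -> resnet34-ald -> alpd-net} is
#' reproducible by flags alone.
#'
#' @param preset One of `"alpd-net"`, `"resnet34-d"`, `"resnet34-ad"`,
#'   `"resnet34-ald"`, or `"custom"`. Presets set the three module flags;
#'   `"custom"` leaves them as given.
#' @param image_size Network input side in pixels; must be divisible by 32.
#' @param n_classes Number of object classes (3 licorice species).
#' @param widths Stage output channel counts.
#' @param blocks Number of BasicBlocks per stage.
#' @param enable_absm,enable_lmsm,enable_pffm Module flags (overridden by
#'   non-custom presets).
#' @param absm,lmsm,pffm,head Optional per-module option lists; see
#'   Details. Unnamed entries keep their defaults.
#'
#' @details
#' ABSM options: `heads` (channel-attention heads, default 4),
#' `compress_kernel` (depthwise compression kernel, fixed 7),
#' `compress_stride` (spatial compression stride, default 2),
#' `profile_kernel` (1-D kernel on pooled coordinate profiles, default 3).
#' LMSM options: `dilations` (default 1:4), `reduction` (channel reduction
#' ratio, default 16), `inner_cap`/`inner_min` (bounds on the reduced
#' width, defaults 16/4), `local_pool` (local average-pool size, default
#' 2), `kernel1d` (channel 1-D kernel, default 3).
#' PFFM options: `heads` (default 4), `kv_tokens` (key/value token budget
#' of each WSAF attention, default 340).
#' Head options: `branch_width` (per-level widths of the two head
#' branches, default `c(128, 160, 168)`).
#'
#' The numeric defaults that the original description of the architecture
#' leaves open (compression stride, head count, reduction ratios, token
#' budget, head widths) are calibrated so that the per-preset FLOP totals
#' land on the published complexity budget of each ablation stage; see
#' `vignette("alpdnet-methods")`.
#'
#' @return An object of class `"alpd_config"`: a nested list with elements
#'   `preset`, `image_size`, `n_classes`, `widths`, `blocks`, `strides`,
#'   `enable_absm`, `enable_lmsm`, `enable_pffm`, `absm`, `lmsm`, `pffm`,
#'   `head`.
#' @examples
#' cfg <- alpd_config("resnet34-d")
#' cfg$enable_absm
#' @export
alpd_config <- function(preset = c("alpd-net", "resnet34-d", "resnet34-ad",
                                   "resnet34-ald", "custom"),
                        image_size = 640L, n_classes = 3L,
                        widths = c(64L, 128L, 256L, 512L),
                        blocks = c(3L, 4L, 6L, 3L),
                        enable_absm = TRUE, enable_lmsm = TRUE,
                        enable_pffm = TRUE,
                        absm = list(), lmsm = list(), pffm = list(),
                        head = list()) {
  preset <- match.arg(preset)
  flags <- switch(preset,
    "resnet34-d"   = c(FALSE, FALSE, FALSE),
    "resnet34-ad"  = c(TRUE, FALSE, FALSE),
    "resnet34-ald" = c(TRUE, TRUE, FALSE),
    "alpd-net"     = c(TRUE, TRUE, TRUE),
    "custom"       = c(enable_absm, enable_lmsm, enable_pffm))
  if (image_size <= 0 || image_size %% 32L != 0L)
    stop("image_size must be a positive multiple of 32")
  if (length(widths) != 4L || length(blocks) != 4L)
    stop("widths and blocks must each have 4 entries")

  absm <- modifyList(list(heads = 4L, compress_kernel = 7L,
                          compress_stride = 2L, profile_kernel = 3L), absm)
  lmsm <- modifyList(list(dilations = 1:4, reduction = 16L,
                          inner_cap = 16L, inner_min = 4L,
                          local_pool = 2L, kernel1d = 3L), lmsm)
  pffm <- modifyList(list(heads = 4L, kv_tokens = 340L), pffm)
  head <- modifyList(list(branch_width = c(128L, 160L, 168L)), head)

  if (absm$compress_kernel != 7L)
    stop("ABSM compression kernel is fixed at 7")
  if (absm$compress_stride < 1L) stop("ABSM compress_stride must be >= 1")
  if (any(widths %% absm$heads != 0L))
    stop("every stage width must be divisible by the ABSM head count")
  if (any(diff(lmsm$dilations) <= 0) || any(lmsm$dilations < 1))
    stop("LMSM dilations must be strictly increasing positive integers")
  inner <- lmsm_inner_width(widths, lmsm)
  if (any(inner %% 4L != 0L))
    stop("LMSM reduced width must be divisible by 4 (one slice per dilation)")

  structure(list(
    preset = preset, image_size = as.integer(image_size),
    n_classes = as.integer(n_classes),
    widths = as.integer(widths), blocks = as.integer(blocks),
    strides = c(1L, 2L, 2L, 2L),
    enable_absm = flags[1], enable_lmsm = flags[2], enable_pffm = flags[3],
    absm = absm, lmsm = lmsm, pffm = pffm, head = head
  ), class = "alpd_config")
}

# Reduced LMSM width per stage: width/reduction clamped to [inner_min, inner_cap].
lmsm_inner_width <- function(widths, lmsm) {
  pmax(lmsm$inner_min, pmin(lmsm$inner_cap, widths %/% lmsm$reduction))
}

# Pyramid (a, b, c) = deepest..shallowest taps at strides 32/16/8.
pyramid_channels <- function(cfg) {
  c(a = cfg$widths[4], b = cfg$widths[3], c = cfg$widths[2])
}

#' @export
print.alpd_config <- function(x, ...) {
  cat("<alpd_config> preset:", x$preset, "\n")
  cat("  input:", x$image_size, "x", x$image_size, " classes:", x$n_classes, "\n")
  cat("  stages:", paste(x$blocks, collapse = "/"),
      "blocks, widths", paste(x$widths, collapse = "/"), "\n")
  cat("  modules: ABSM=", x$enable_absm, " LMSM=", x$enable_lmsm,
      " PFFM=", x$enable_pffm, "\n", sep = "")
  invisible(x)
}
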