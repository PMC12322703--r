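#' Adaptive background-suppression module (ABSM)
#'
#' Channel refinement followed by coordinate-aware spatial gating, designed
#' to damp responses from cluttered vegetated backgrounds. The module
#' first compresses the map spatially with a depthwise 7x7 convolution,
#' runs multi-head self-attention *across channels* (each channel token is
#' embedded as its flattened compressed response; queries/keys/values come
#' from depthwise 7x7 projections), pools the attention output and takes a
#' softmax over channels to obtain per-channel weights. The input is
#' rescaled by `C * weight` so that uniform weights leave it unchanged.
#' The spatial stage pools per-pixel channel mean/max statistics into
#' horizontal and vertical coordinate profiles, refines them with a shared
#' 1-D convolution, collapses each to a single channel, and gates the
#' channel-refined map by the outer product of the two sigmoid profiles.
#' All projections are bias-free, so with every convolution weight at zero
#' the channel stage is the identity and the output is exactly 0.25 times
#' the input.
#'
#' @name absm
#' @keywords internal
NULL

absm_new <- function(C, absm_cfg) {
  if (C %% absm_cfg$heads != 0L)
    stop("ABSM: channels must be divisible by the head count")
  s <- absm_cfg$compress_stride
  k <- absm_cfg$compress_kernel
  kp <- absm_cfg$profile_kernel
  ch <- list(
    compress = layer_conv2d(k, C, C, stride = s, pad = (k - 1L) %/% 2L,
                            groups = C),
    q = layer_conv2d(k, C, C, groups = C),
    k = layer_conv2d(k, C, C, groups = C),
    v = layer_conv2d(k, C, C, groups = C),
    profile = layer_conv1d(kp, 2L, 2L),
    collapse_h = layer_conv1d(1L, 2L, 1L),
    collapse_w = layer_conv1d(1L, 2L, 1L))
  m <- new_module("absm", children = ch)
  m$forward <- function(x, training = TRUE) {
    d <- dim(x$v); H <- d[1]; W <- d[2]; N <- d[4]
    if (H < s || W < s) stop("ABSM: input smaller than compress stride")
    cm <- ch$compress$forward(x, training)
    q <- ch$q$forward(cm, training)
    kk <- ch$k$forward(cm, training)
    v <- ch$v$forward(cm, training)
    pooled <- ag_channel_attention(q, kk, v, absm_cfg$heads)   # (C, N)
    if (.trace$active) {
      dc <- dim(cm$v)
      trace_push(attn_flop_row("trace", "absm.chan_attn", C, C,
                               dc[1] * dc[2]))
    }
    wts <- ag_softmax_chan(ag_reshape(pooled, c(1, 1, C, N)))
    f1 <- ag_mul_b(x, ag_scale(wts, C))
    stats <- ag_chan_stats(f1)                                 # (H,W,2,N)
    ph <- ag_reshape(ag_axis_mean(stats, 2L), c(H, 2, N))      # width pooled
    pw <- ag_reshape(ag_axis_mean(stats, 1L), c(W, 2, N))      # height pooled
    ph <- ch$profile$forward(ph, training)
    pw <- ch$profile$forward(pw, training)
    sh <- ag_sigmoid(ag_reshape(ch$collapse_h$forward(ph, training),
                                c(H, 1, 1, N)))
    sw <- ag_sigmoid(ag_reshape(ch$collapse_w$forward(pw, training),
                                c(1, W, 1, N)))
    out <- ag_mul_b(ag_mul_b(f1, sh), sw)
    attr(out, "channel_weights") <- wts
    out
  }
  m$channel_weights <- function(x, training = FALSE) {
    cm <- ch$compress$forward(x, training)
    pooled <- ag_channel_attention(ch$q$forward(cm, training),
                                   ch$k$forward(cm, training),
                                   ch$v$forward(cm, training),
                                   absm_cfg$heads)
    d <- dim(x$v)
    ag_softmax_chan(ag_reshape(pooled, c(1, 1, d[3], d[4])))
  }
  m
}
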