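#' Progressive feature-fusion module (PFFM) and WSAF operator
#'
#' WSAF (weighted self-attention fusion) combines two feature maps: the
#' non-target operand is bilinearly resampled to the target resolution and
#' projected to the target channel count by a 1x1 convolution; the maps
#' are summed with learnable scalar weights `W1` (first operand) and `W2`
#' (second operand), both initialized at 1; a per-channel gate
#' `sigmoid(global_avg_pool(F1))` rescales the sum and is added back
#' (`z = g * F1 + F1`); finally transformer-style multi-head
#' self-attention over spatial tokens (keys/values pooled to a token
#' budget, all projections bias-free) refines the result residually
#' (`out = z + MHSA(z)`).
#'
#' The neck computes `ab = WSAF(a, b)` and `bc = WSAF(b, c)` once each and
#' shares them: `A = WSAF(a, bc)` (stride 32), `B = WSAF(ab, bc)` produced
#' at stride 16 by aligning the first operand onto the second, and
#' `C = WSAF(c, ab)` (stride 8) - five distinct WSAF units in total.
#'
#' @name pffm
#' @keywords internal
NULL

# align_op: which operand is resampled+projected (the other sets the
# output resolution and channel count). Weight W1 always belongs to the
# first operand, W2 to the second.
wsaf_new <- function(c_out, c_align, heads, kv_tokens, align_op = 2L) {
  force(c_out); force(c_align); force(heads); force(kv_tokens)
  force(align_op)
  ch <- list(align = layer_conv2d(1L, c_align, c_out),
             wq = layer_linear(c_out, c_out),
             wk = layer_linear(c_out, c_out),
             wv = layer_linear(c_out, c_out),
             wo = layer_linear(c_out, c_out),
             w1 = layer_scalar(1),
             w2 = layer_scalar(1))
  m <- new_module("wsaf", children = ch)
  m$forward <- function(f01, f02, training = TRUE) {
    if (align_op == 2L) {
      tgt <- f01
      al <- ch$align$forward(ag_resize(f02, dim(f01$v)[1], dim(f01$v)[2]),
                             training)
      f1 <- ag_add(ag_smul(tgt, ch$w1$s), ag_smul(al, ch$w2$s))
    } else {
      tgt <- f02
      al <- ch$align$forward(ag_resize(f01, dim(f02$v)[1], dim(f02$v)[2]),
                             training)
      f1 <- ag_add(ag_smul(al, ch$w1$s), ag_smul(tgt, ch$w2$s))
    }
    g <- ag_sigmoid(ag_gap(f1))
    z <- ag_add(ag_mul_b(f1, g), f1)
    d <- dim(z$v)
    kv <- min(kv_tokens, d[1] * d[2])
    attn <- ag_mhsa_spatial(z, ch$wq$w, ch$wk$w, ch$wv$w, ch$wo$w,
                            heads, kv_tokens)
    if (.trace$active) {
      trace_push(conv1d_flop_row("trace", "wsaf.attn_k", 1L, c_out, c_out,
                                 kv))
      trace_push(conv1d_flop_row("trace", "wsaf.attn_v", 1L, c_out, c_out,
                                 kv))
      trace_push(conv_flop_row("trace", "wsaf.attn_q", 1L, c_out, c_out,
                               d[1], d[2]))
      trace_push(conv_flop_row("trace", "wsaf.attn_o", 1L, c_out, c_out,
                               d[1], d[2]))
      trace_push(attn_flop_row("trace", "wsaf.attn", d[1] * d[2], kv,
                               c_out))
    }
    ag_add(z, attn)
  }
  m
}

pffm_new <- function(cfg) {
  pc <- pyramid_channels(cfg)
  h <- cfg$pffm$heads; kv <- cfg$pffm$kv_tokens
  ch <- list(
    u_ab = wsaf_new(pc[["a"]], pc[["b"]], h, kv),
    u_bc = wsaf_new(pc[["b"]], pc[["c"]], h, kv),
    u_A = wsaf_new(pc[["a"]], pc[["b"]], h, kv),
    u_B = wsaf_new(pc[["b"]], pc[["a"]], h, kv, align_op = 1L),
    u_C = wsaf_new(pc[["c"]], pc[["a"]], h, kv))
  m <- new_module("pffm", children = ch)
  m$forward <- function(pyr, training = TRUE) {
    ab <- ch$u_ab$forward(pyr$a, pyr$b, training)
    bc <- ch$u_bc$forward(pyr$b, pyr$c, training)
    list(A = ch$u_A$forward(pyr$a, bc, training),
         B = ch$u_B$forward(ab, bc, training),
         C = ch$u_C$forward(pyr$c, ab, training))
  }
  m
}
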