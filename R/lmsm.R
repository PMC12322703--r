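#' Lightweight multi-scale module (LMSM)
#'
#' Two branches. The channel-information branch applies local average
#' pooling, then global average pooling, integrates the resulting channel
#' vector with a 1-D convolution along the channel axis, and broadcasts
#' ("anti-pools") it back to the input resolution. The multi-scale branch
#' reduces channels with a 1x1 convolution, splits the reduced map into
#' four equal channel slices, passes each slice through a 3x3 convolution
#' with a distinct dilation rate (padding = dilation, so spatial size is
#' preserved and a rate-d kernel sees a (2d+1)^2 receptive field),
#' concatenates, and restores the channel count with a second 1x1
#' convolution. The output is `branch2 * sigmoid(branch1) + x`, so zeroed
#' branch-2 weights reduce the module to the identity.
#'
#' @name lmsm
#' @keywords internal
NULL

lmsm_new <- function(C, lmsm_cfg) {
  w_in <- lmsm_inner_width(C, lmsm_cfg)
  if (w_in %% 4L != 0L)
    stop("LMSM: reduced width must be divisible by 4")
  slice <- w_in %/% 4L
  dils <- lmsm_cfg$dilations
  ch <- list(chan1d = layer_conv1d(lmsm_cfg$kernel1d, 1L, 1L),
             reduce = layer_conv2d(1L, C, w_in),
             restore = layer_conv2d(1L, w_in, C))
  for (i in seq_along(dils))
    ch[[paste0("dil", i)]] <- layer_conv2d(3L, slice, slice,
                                           pad = dils[i],
                                           dilation = dils[i])
  m <- new_module("lmsm", children = ch)
  m$forward <- function(x, training = TRUE) {
    d <- dim(x$v); N <- d[4]
    p <- lmsm_cfg$local_pool
    # branch 1: local + global pooling, channel 1-D integration, anti-pool
    loc <- if (d[1] >= p && d[2] >= p) ag_avgpool(x, p) else x
    cv <- ag_reshape(ag_gap(loc), c(C, 1, N))
    cv <- ch$chan1d$forward(cv, training)
    gate <- ag_sigmoid(ag_reshape(cv, c(1, 1, C, N)))
    # branch 2: grouped multi-dilation extraction
    red <- ch$reduce$forward(x, training)
    parts <- vector("list", length(dils))
    for (i in seq_along(dils)) {
      sl <- ag_op(red$v[, , ((i - 1L) * slice + 1L):(i * slice), ,
                        drop = FALSE],
                  list(red), local({
                    ii <- i
                    function(g) {
                      dr <- array(0, dim = dim(red$v))
                      dr[, , ((ii - 1L) * slice + 1L):(ii * slice), ] <- g
                      list(dr)
                    }
                  }))
      parts[[i]] <- ch[[paste0("dil", i)]]$forward(sl, training)
    }
    cat_v <- array(0, c(d[1], d[2], w_in, N))
    for (i in seq_along(parts))
      cat_v[, , ((i - 1L) * slice + 1L):(i * slice), ] <- parts[[i]]$v
    cat2 <- ag_op(cat_v, parts,
      function(g) lapply(seq_along(parts), function(i)
        g[, , ((i - 1L) * slice + 1L):(i * slice), , drop = FALSE]))
    b2 <- ch$restore$forward(cat2, training)
    ag_add(ag_mul_b(b2, gate), x)
  }
  m
}
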