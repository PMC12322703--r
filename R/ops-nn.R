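# Neural-network operations on (H, W, C, N) feature maps, built on the
# autograd core and the compiled im2col / pooling / resize kernels.

conv_out_len <- function(L, k, pad, stride, dil)
  (L + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L

# 2-D convolution, bias-free. `w` has dim (k, k, C_in/groups, C_out).
ag_conv2d <- function(x, w, stride = 1L, pad = 0L, dilation = 1L,
                      groups = 1L) {
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w$v); kh <- wd[1]; kw <- wd[2]; cing <- wd[3]; cout <- wd[4]
  stopifnot(kh == kw, C == cing * groups, cout %% groups == 0L)
  k <- kh
  Hout <- conv_out_len(H, k, pad, stride, dilation)
  Wout <- conv_out_len(W, k, pad, stride, dilation)
  if (groups == C && cout == C) {   # depthwise fast path
    y <- array(cpp_dwconv(x$v, w$v, H, W, C, N,
                          k, pad, stride, dilation),
               c(Hout, Wout, C, N))
    return(ag_op(y, list(x, w), function(gr) {
      list(array(cpp_dwconv_dx(gr, w$v, H, W, C,
                               N, k, pad, stride, dilation), d),
           array(cpp_dwconv_dw(gr, x$v, H, W, C,
                               N, k, pad, stride, dilation), wd))
    }))
  }
  y <- array(cpp_conv2d_fwd(x$v, w$v, H, W, C, N,
                            k, cout, groups, pad, stride, dilation),
             c(Hout, Wout, cout, N))
  ag_op(y, list(x, w), function(gr) {
    r <- cpp_conv2d_bwd(gr, x$v, w$v,
                        H, W, C, N, k, cout, groups, pad, stride,
                        dilation)
    list(array(r$dx, d), array(r$dw, wd))
  })
}

# 1-D convolution over sequences stored as (L, C, N); `w` dim (k, C_in, C_out).
ag_conv1d <- function(x, w, pad = 0L) {
  d <- dim(x$v); L <- d[1]; C <- d[2]; N <- d[3]
  wd <- dim(w$v); k <- wd[1]; cout <- wd[3]
  stopifnot(wd[2] == C)
  Lout <- L + 2L * pad - k + 1L
  xp <- array(0, dim = c(L + 2L * pad, C, N))
  xp[pad + seq_len(L), , ] <- x$v
  y <- array(0, dim = c(Lout, cout, N))
  for (j in seq_len(k)) {
    segA <- array(xp[(j - 1L) + seq_len(Lout), , , drop = FALSE],
                  c(Lout, C, N))
    for (n in seq_len(N))
      y[, , n] <- y[, , n] + matrix(segA[, , n], Lout, C) %*%
        matrix(w$v[j, , ], C, cout)
  }
  ag_op(y, list(x, w), function(gr) {
    dxp <- array(0, dim = dim(xp))
    dw <- array(0, dim = wd)
    for (j in seq_len(k)) {
      idx <- (j - 1L) + seq_len(Lout)
      wj <- matrix(w$v[j, , ], C, cout)
      for (n in seq_len(N)) {
        gn <- matrix(gr[, , n], Lout, cout)
        dxp[idx, , n] <- dxp[idx, , n] + gn %*% t(wj)
        dw[j, , ] <- dw[j, , ] +
          matrix(crossprod(matrix(xp[idx, , n], Lout, C), gn), C, cout)
      }
    }
    list(array(dxp[pad + seq_len(L), , , drop = FALSE], d), dw)
  })
}

# per-channel sum / mean over (H, W, N) of an (H, W, C, N) array, without
# apply(): column sums of the (H*W, C*N) view folded over N
chan_sum <- function(x, d) {
  rowSums(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# recycle a per-channel vector over (H, W, C, N) via column-major layout:
# rep(v, each = H*W) recycles across N automatically in arithmetic
chan_rep <- function(v, d) rep(v, each = d[1] * d[2])

# Batch normalization over (H, W, N) per channel. `state` carries running
# moments; gamma/beta are length-C tensors.
ag_bn2d <- function(x, gamma, beta, state, training = TRUE,
                    momentum = 0.1, eps = 1e-5) {
  d <- dim(x$v); C <- d[3]
  m <- d[1] * d[2] * d[4]
  if (training && m > 1) {
    mu <- chan_sum(x$v, d) / m
    va <- chan_sum(x$v * x$v, d) / m - mu^2
    va <- pmax(va, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x$v - chan_rep(mu, d)) * chan_rep(invstd, d)
  dim(xhat) <- d
  y <- xhat * chan_rep(gamma$v, d) + chan_rep(beta$v, d)
  dim(y) <- d
  use_batch <- training && m > 1
  ag_op(y, list(x, gamma, beta), function(gr) {
    dgamma <- chan_sum(gr * xhat, d)
    dbeta <- chan_sum(gr, d)
    if (use_batch) {
      dxh <- gr * chan_rep(gamma$v, d)
      s1 <- chan_sum(dxh, d)
      s2 <- chan_sum(dxh * xhat, d)
      dx <- chan_rep(invstd / m, d) *
        (m * dxh - chan_rep(s1, d) - xhat * chan_rep(s2, d))
      dim(dx) <- d
    } else {
      dx <- gr * chan_rep(gamma$v * invstd, d)
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

ag_maxpool <- function(x, k, stride, pad = 0L) {
  d <- dim(x$v)
  r <- cpp_maxpool(x$v, d[1], d[2], d[3], d[4], k, stride, pad)
  y <- array(r$y, c(r$Hout, r$Wout, d[3], d[4]))
  ag_op(y, list(x), function(gr)
    list(array(cpp_maxpool_grad(gr, r$arg, prod(d)), d)))
}

ag_avgpool <- function(x, k, stride = k) {
  d <- dim(x$v)
  Hout <- (d[1] - k) %/% stride + 1L; Wout <- (d[2] - k) %/% stride + 1L
  y <- array(cpp_avgpool(x$v, d[1], d[2], d[3], d[4], k, stride),
             c(Hout, Wout, d[3], d[4]))
  ag_op(y, list(x), function(gr)
    list(array(cpp_avgpool_grad(as.numeric(gr), d[1], d[2], d[3], d[4],
                                k, stride), d)))
}

ag_resize <- function(x, Hout, Wout) {
  d <- dim(x$v)
  if (d[1] == Hout && d[2] == Wout) return(x)
  y <- array(cpp_resize_bilinear(x$v, d[1], d[2], d[3], d[4],
                                 Hout, Wout), c(Hout, Wout, d[3], d[4]))
  ag_op(y, list(x), function(gr)
    list(array(cpp_resize_bilinear_grad(gr, d[1], d[2], d[3],
                                        d[4], Hout, Wout), d)))
}

# global average pool -> (1, 1, C, N)
ag_gap <- function(x) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  y <- array(colMeans(matrix(x$v, hw, d[3] * d[4])), c(1, 1, d[3], d[4]))
  ag_op(y, list(x), function(gr)
    list(array(rep(as.numeric(gr) / hw, each = hw), d)))
}

# mean over one spatial axis: axis 1 pools H away -> (1, W, C, N); axis 2
# pools W away -> (H, 1, C, N)
ag_axis_mean <- function(x, axis) {
  d <- dim(x$v)
  if (axis == 1L) {
    y <- array(colMeans(matrix(x$v, d[1], d[2] * d[3] * d[4])),
               c(1, d[2], d[3], d[4]))
  } else {
    xp <- aperm(array(x$v, c(d[1], d[2], d[3] * d[4])), c(2, 1, 3))
    y <- array(colMeans(matrix(xp, d[2], d[1] * d[3] * d[4])),
               c(d[1], 1, d[3], d[4]))
  }
  ag_op(y, list(x), function(gr)
    list(bcast_expand(gr, d) / d[axis]))
}

# per-pixel channel statistics: mean and max over C -> (H, W, 2, N)
ag_chan_stats <- function(x) {
  d <- dim(x$v); C <- d[3]
  hwn <- d[1] * d[2] * d[4]
  xp <- aperm(x$v, c(1, 2, 4, 3))          # (H, W, N, C)
  m <- matrix(xp, hwn, C)
  mn <- rowMeans(m)
  jmx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(hwn), jmx)]
  y <- array(0, c(d[1], d[2], 2, d[4]))
  y[, , 1, ] <- mn; y[, , 2, ] <- mx
  ag_op(y, list(x), function(gr) {
    g1 <- as.numeric(gr[, , 1, , drop = FALSE])
    g2 <- as.numeric(gr[, , 2, , drop = FALSE])
    dm <- matrix(g1 / C, hwn, C)
    dm[cbind(seq_len(hwn), jmx)] <- dm[cbind(seq_len(hwn), jmx)] + g2
    list(aperm(array(dm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

# softmax across channels of a (1, 1, C, N) map
ag_softmax_chan <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[3], d[4])
  e <- exp(sweep(m, 2, apply(m, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  ag_op(array(p, d), list(x), function(gr) {
    gm <- matrix(gr, d[3], d[4])
    dv <- p * sweep(gm, 2, colSums(gm * p))
    list(array(dv, d))
  })
}

# sample n of a feature map as a (H*W, C) token matrix (tokens in raster order)
ag_sample_mat <- function(x, n) {
  d <- dim(x$v)
  m <- matrix(x$v[, , , n], d[1] * d[2], d[3])
  ag_op(m, list(x), function(gr) {
    dx <- array(0, dim = d)
    dx[, , , n] <- array(gr, c(d[1], d[2], d[3]))
    list(dx)
  })
}

# stack per-sample (H*W, C) token matrices back into (H, W, C, N)
ag_stack_mats <- function(mats, H, W, C) {
  N <- length(mats)
  y <- array(0, c(H, W, C, N))
  for (n in seq_len(N)) y[, , , n] <- array(mats[[n]]$v, c(H, W, C))
  ag_op(y, mats, function(gr)
    lapply(seq_len(N), function(n)
      matrix(gr[, , , n], H * W, C)))
}

# 1-D adaptive average pooling of token rows: (T, C) -> (kv, C)
ag_segpool_rows <- function(x, kv) {
  Tn <- nrow(x$v)
  if (Tn <= kv) return(x)
  starts <- floor((seq_len(kv) - 1L) * Tn / kv) + 1L
  ends <- floor(seq_len(kv) * Tn / kv)
  P <- matrix(0, kv, Tn)
  for (i in seq_len(kv)) P[i, starts[i]:ends[i]] <- 1 / (ends[i] - starts[i] + 1L)
  ag_op(P %*% x$v, list(x), function(gr) list(crossprod(P, gr)))
}

ag_rowmeans <- function(x) {
  nc <- ncol(x$v)
  ag_op(matrix(rowMeans(x$v), nrow(x$v), 1), list(x), function(gr)
    list(matrix(gr, nrow(x$v), nc) / nc))
}

# Multi-head self-attention over spatial tokens of z (H, W, C, N).
# Dense bias-free projections Wq/Wk/Wv/Wo (C x C); keys and values are
# segment-pooled to at most `kv_tokens` tokens. Returns attention output
# (without residual) shaped like z.
ag_mhsa_spatial <- function(z, Wq, Wk, Wv, Wo, heads, kv_tokens) {
  d <- dim(z$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    X <- ag_sample_mat(z, n)
    Xp <- ag_segpool_rows(X, kv_tokens)
    Q <- ag_matmul(X, Wq)
    K <- ag_matmul(Xp, Wk)
    V <- ag_matmul(Xp, Wv)
    hs <- vector("list", heads)
    for (h in seq_len(heads)) {
      j <- ((h - 1L) * dh + 1L):(h * dh)
      S <- ag_scale(ag_matmul(ag_cols(Q, j), ag_t(ag_cols(K, j))),
                    1 / sqrt(dh))
      A <- ag_softmax_rows(S)
      hs[[h]] <- ag_matmul(A, ag_cols(V, j))
    }
    outs[[n]] <- ag_matmul(ag_cbind(hs), Wo)
  }
  ag_stack_mats(outs, H, W, C)
}

# Multi-head self-attention over channel tokens of a compressed map
# (Hc, Wc, C, N): each channel is a token embedded as its flattened spatial
# response (length d = Hc*Wc). q/k/v are depthwise-convolved variants of the
# map (computed by the caller); returns the (C, N) vector of attention
# outputs pooled over the embedding axis.
ag_channel_attention <- function(q, k, v, heads) {
  d <- dim(q$v); Hc <- d[1]; Wc <- d[2]; C <- d[3]; N <- d[4]
  dt <- Hc * Wc
  heads <- min(heads, dt)   # embedding axis is split across heads
  bounds <- floor(seq(0, dt, length.out = heads + 1L))
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    Qm <- ag_t(ag_sample_mat(q, n))   # (C, dt)
    Km <- ag_t(ag_sample_mat(k, n))
    Vm <- ag_t(ag_sample_mat(v, n))
    hs <- vector("list", heads)
    for (h in seq_len(heads)) {
      j <- (bounds[h] + 1L):bounds[h + 1L]
      dhh <- length(j)
      S <- ag_scale(ag_matmul(ag_cols(Qm, j), ag_t(ag_cols(Km, j))),
                    1 / sqrt(max(1, dhh)))
      A <- ag_softmax_rows(S)          # (C, C)
      hs[[h]] <- ag_matmul(A, ag_cols(Vm, j))
    }
    outs[[n]] <- ag_rowmeans(ag_cbind(hs))   # (C, 1)
  }
  ag_op(do.call(cbind, lapply(outs, function(o) o$v)), outs, function(gr)
    lapply(seq_len(N), function(n) gr[, n, drop = FALSE]))
}
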