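# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Tensors are environments holding a value `v` (numeric array of any rank),
# an optional accumulated gradient `grad`, the parent nodes and a backward
# closure mapping the upstream gradient to one gradient per parent. The
# graph is built eagerly on every forward pass; ag_backward() topologically
# sorts the tape and accumulates gradients. All operations are
# double-precision; shapes follow the (H, W, C, N) layout used by the
# convolution kernels where spatial structure matters.

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0

ag <- function(value, requires = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_state$counter <- .ag_state$counter + 1
  e$id <- as.character(.ag_state$counter)
  e$v <- value
  e$grad <- NULL
  e$parents <- list()
  e$bw <- NULL
  e$req <- requires
  e$name <- name
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_const <- function(value) ag(value, requires = FALSE)

# Generic node constructor. `backward` receives the upstream gradient (an
# array shaped like `value`) and must return a list of gradients, one per
# parent (NULL allowed for parents that need no gradient).
ag_op <- function(value, parents, backward) {
  e <- ag(value)
  e$parents <- parents
  e$bw <- backward
  e$req <- any(vapply(parents, function(p) p$req, logical(1)))
  e
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Reverse pass from a scalar (or any) root. Seeds with ones unless `seed`
# is given. Gradients accumulate into each node's `grad` field.
ag_backward <- function(root, seed = NULL) {
  stopifnot(is_ag(root))
  # iterative post-order DFS
  topo <- vector("list", 64L); nt <- 0L
  stack <- list(list(node = root, stage = 1L)); ns <- 1L
  seen <- new.env(parent = emptyenv())
  key <- function(e) e$id
  while (ns > 0L) {
    fr <- stack[[ns]]; ns <- ns - 1L
    nd <- fr$node
    k <- key(nd)
    if (fr$stage == 1L) {
      if (!is.null(seen[[k]])) next
      seen[[k]] <- TRUE
      ns <- ns + 1L; stack[[ns]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (p$req && is.null(seen[[key(p)]])) {
          ns <- ns + 1L; stack[[ns]] <- list(node = p, stage = 1L)
        }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- nd
    }
  }
  root$grad <- if (is.null(seed)) array(1, dim = dim_of(root$v)) else seed
  for (i in seq(nt, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$req || is.null(gs[[j]])) next
      g <- gs[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

dim_of <- function(v) if (is.null(dim(v))) length(v) else dim(v)

keep_dim <- function(g, v) { dim(g) <- dim(v); g }

# ---- elementwise arithmetic (same shape, or numeric scalar operand) --------

wrap2 <- function(a, b) {
  if (!is_ag(a)) a <- ag_const(a)
  if (!is_ag(b)) b <- ag_const(b)
  list(a, b)
}

ag_add <- function(a, b) {
  p <- wrap2(a, b)
  ag_op(p[[1]]$v + p[[2]]$v, p, function(g)
    list(keep_dim(g, p[[1]]$v), keep_dim(g, p[[2]]$v)))
}

ag_sub <- function(a, b) {
  p <- wrap2(a, b)
  ag_op(p[[1]]$v - p[[2]]$v, p, function(g)
    list(keep_dim(g, p[[1]]$v), keep_dim(-g, p[[2]]$v)))
}

ag_mul <- function(a, b) {
  p <- wrap2(a, b)
  ag_op(p[[1]]$v * p[[2]]$v, p, function(g)
    list(keep_dim(g * p[[2]]$v, p[[1]]$v), keep_dim(g * p[[1]]$v, p[[2]]$v)))
}

ag_div <- function(a, b) {
  p <- wrap2(a, b)
  ag_op(p[[1]]$v / p[[2]]$v, p, function(g)
    list(keep_dim(g / p[[2]]$v, p[[1]]$v),
         keep_dim(-g * p[[1]]$v / p[[2]]$v^2, p[[2]]$v)))
}

ag_scale <- function(x, a) {  # multiply by a fixed numeric scalar
  ag_op(x$v * a, list(x), function(g) list(g * a))
}

ag_neg <- function(x) ag_scale(x, -1)

ag_exp <- function(x) {
  y <- exp(x$v)
  ag_op(y, list(x), function(g) list(g * y))
}

ag_log <- function(x) ag_op(log(x$v), list(x), function(g) list(g / x$v))

ag_sqrt <- function(x) {
  y <- sqrt(x$v)
  ag_op(y, list(x), function(g) list(g / (2 * y)))
}

ag_square <- function(x) ag_op(x$v^2, list(x), function(g) list(2 * g * x$v))

ag_atan <- function(x)
  ag_op(atan(x$v), list(x), function(g) list(g / (1 + x$v^2)))

ag_relu <- function(x) {
  m <- x$v > 0
  ag_op(x$v * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  ag_op(y, list(x), function(g) list(g * y * (1 - y)))
}

# log(1 + exp(x)), overflow-safe; derivative sigmoid(x)
ag_softplus <- function(x) {
  y <- pmax(x$v, 0) + log1p(exp(-abs(x$v)))
  dim(y) <- dim(x$v)
  ag_op(y, list(x), function(g) list(g / (1 + exp(-x$v))))
}

ag_max2 <- function(a, b) {  # elementwise max; gradient routed to argmax
  p <- wrap2(a, b)
  m <- p[[1]]$v >= p[[2]]$v
  ag_op(pmax(p[[1]]$v, p[[2]]$v), p, function(g)
    list(keep_dim(g * m, p[[1]]$v), keep_dim(g * !m, p[[2]]$v)))
}

ag_min2 <- function(a, b) {
  p <- wrap2(a, b)
  m <- p[[1]]$v <= p[[2]]$v
  ag_op(pmin(p[[1]]$v, p[[2]]$v), p, function(g)
    list(keep_dim(g * m, p[[1]]$v), keep_dim(g * !m, p[[2]]$v)))
}

ag_clamp <- function(x, lo, hi) {
  inside <- x$v >= lo & x$v <= hi
  ag_op(pmin(pmax(x$v, lo), hi), list(x), function(g)
    list(keep_dim(g * inside, x$v)))
}

ag_sum <- function(x)
  ag_op(sum(x$v), list(x), function(g)
    list(array(as.numeric(g), dim = dim_of(x$v))))

ag_mean <- function(x) {
  n <- length(x$v)
  ag_op(sum(x$v) / n, list(x), function(g)
    list(array(as.numeric(g) / n, dim = dim_of(x$v))))
}

# ---- matrix / indexing primitives ------------------------------------------

ag_matmul <- function(a, b) {
  ag_op(a$v %*% b$v, list(a, b), function(g)
    list(g %*% t(b$v), t(a$v) %*% g))
}

ag_t <- function(x) ag_op(t(x$v), list(x), function(g) list(t(g)))

ag_reshape <- function(x, d) {
  v <- x$v; dim(v) <- d
  ag_op(v, list(x), function(g) { dim(g) <- dim_of(x$v); list(g) })
}

ag_cols <- function(x, j) {  # column subset of a matrix
  ag_op(x$v[, j, drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = dim(x$v)); dx[, j] <- g; list(dx)
  })
}

ag_rows <- function(x, i) {
  ag_op(x$v[i, , drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = dim(x$v)); dx[i, ] <- dx[i, ] + g; list(dx)
  })
}

ag_cbind <- function(xs) {
  widths <- vapply(xs, function(x) ncol(x$v), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ag_op(do.call(cbind, lapply(xs, function(x) x$v)), xs, function(g)
    lapply(seq_along(xs), function(i)
      g[, starts[i]:ends[i], drop = FALSE]))
}

ag_softmax_rows <- function(x) {
  m <- x$v - apply(x$v, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_op(p, list(x), function(g)
    list(p * (g - rowSums(g * p))))
}

# ---- broadcasting over singleton axes --------------------------------------

# expand array `m` (with singleton axes) to dims `d`
bcast_expand <- function(m, d) {
  dm <- dim_of(m)
  stopifnot(length(dm) == length(d), all(dm == d | dm == 1L))
  if (all(dm == d)) return(m)
  args <- lapply(seq_along(d), function(i)
    if (dm[i] == 1L) rep(1L, d[i]) else seq_len(d[i]))
  do.call(`[`, c(list(m), args, list(drop = FALSE)))
}

# sum `g` (dims d) down to dims `dm` (with singleton axes)
bcast_reduce <- function(g, dm) {
  d <- dim_of(g)
  if (all(d == dm)) return(g)
  keep <- which(dm > 1L)
  if (length(keep) == 0L) out <- sum(g)
  else out <- apply(g, keep, sum)
  array(out, dim = dm)
}

# elementwise multiply with broadcasting of `m` (singleton axes) against x
ag_mul_b <- function(x, m) {
  me <- bcast_expand(m$v, dim_of(x$v))
  ag_op(x$v * me, list(x, m), function(g)
    list(g * me, bcast_reduce(g * x$v, dim_of(m$v))))
}

ag_add_b <- function(x, m) {
  me <- bcast_expand(m$v, dim_of(x$v))
  ag_op(x$v + me, list(x, m), function(g)
    list(g, bcast_reduce(g, dim_of(m$v))))
}
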