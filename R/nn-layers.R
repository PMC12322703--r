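# Parameterized layers: thin environments holding weight tensors plus a
# forward closure. Layers optionally report their cost to an active FLOP
# trace so a live forward pass can be profiled and cross-checked against
# the analytic accountant.

.trace <- new.env(parent = emptyenv())
.trace$active <- FALSE

trace_start <- function() { .trace$active <- TRUE; .trace$rows <- list() }

trace_stop <- function() {
  .trace$active <- FALSE
  rows <- .trace$rows; .trace$rows <- list()
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

trace_push <- function(row) {
  if (.trace$active) .trace$rows[[length(.trace$rows) + 1L]] <- row
  invisible(NULL)
}

# scalar learnable multiplier
ag_smul <- function(x, s) {
  ag_op(x$v * as.numeric(s$v), list(x, s), function(g)
    list(g * as.numeric(s$v), sum(g * x$v)))
}

new_module <- function(kind, params = list(), children = list(),
                       buffers = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$children <- children
  e$buffers <- buffers
  class(e) <- "nn_module"
  e
}

# depth-first named list of every parameter tensor
collect_params <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params))
    out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  for (nm in names(mod$children))
    out <- c(out, collect_params(mod$children[[nm]],
                                 paste0(prefix, nm, ".")))
  out
}

collect_buffers <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$buffers))
    out[[paste0(prefix, nm)]] <- mod$buffers[[nm]]
  for (nm in names(mod$children))
    out <- c(out, collect_buffers(mod$children[[nm]],
                                  paste0(prefix, nm, ".")))
  out
}

n_params <- function(mod)
  sum(vapply(collect_params(mod), function(p) length(p$v), numeric(1)))

# serializable weights + normalization statistics
module_state <- function(mod) {
  list(params = lapply(collect_params(mod), function(p) p$v),
       buffers = lapply(collect_buffers(mod), function(b)
         list(running_mean = b$running_mean, running_var = b$running_var)))
}

load_module_state <- function(mod, state) {
  ps <- collect_params(mod)
  stopifnot(identical(sort(names(ps)), sort(names(state$params))))
  for (nm in names(ps)) {
    stopifnot(identical(dim_of(ps[[nm]]$v), dim_of(state$params[[nm]])))
    ps[[nm]]$v <- state$params[[nm]]
  }
  bs <- collect_buffers(mod)
  for (nm in names(bs)) {
    bs[[nm]]$running_mean <- state$buffers[[nm]]$running_mean
    bs[[nm]]$running_var <- state$buffers[[nm]]$running_var
  }
  invisible(mod)
}

rnorm_arr <- function(d, sd) array(stats::rnorm(prod(d), sd = sd), dim = d)

layer_conv2d <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                         dilation = 1L, groups = 1L, zero_init = FALSE) {
  force(stride); force(pad); force(dilation); force(groups)
  cing <- cin %/% groups
  sd <- sqrt(2 / (k * k * cing))
  w <- ag(if (zero_init) array(0, c(k, k, cing, cout))
          else rnorm_arr(c(k, k, cing, cout), sd), requires = TRUE)
  m <- new_module("conv2d", params = list(w = w))
  m$forward <- function(x, training = TRUE) {
    y <- ag_conv2d(x, w, stride = stride, pad = pad, dilation = dilation,
                   groups = groups)
    if (.trace$active) {
      d <- dim(y$v)
      trace_push(conv_flop_row("trace", "conv", k, cin, cout, d[1], d[2],
                               groups))
    }
    y
  }
  m
}

layer_conv1d <- function(k, cin, cout, pad = (k - 1L) %/% 2L,
                         zero_init = FALSE) {
  force(pad)
  sd <- sqrt(2 / (k * cin))
  w <- ag(if (zero_init) array(0, c(k, cin, cout))
          else rnorm_arr(c(k, cin, cout), sd), requires = TRUE)
  m <- new_module("conv1d", params = list(w = w))
  m$forward <- function(x, training = TRUE) {
    y <- ag_conv1d(x, w, pad = pad)
    if (.trace$active)
      trace_push(conv1d_flop_row("trace", "conv1d", k, cin, cout,
                                 dim(y$v)[1]))
    y
  }
  m
}

layer_bn2d <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  gamma <- ag(rep(1, C), requires = TRUE)
  beta <- ag(rep(0, C), requires = TRUE)
  m <- new_module("bn2d", params = list(gamma = gamma, beta = beta),
                  buffers = list(bn = st))
  m$forward <- function(x, training = TRUE)
    ag_bn2d(x, gamma, beta, st, training = training)
  m
}

# dense bias-free projection stored as (C_in x C_out) matrix
layer_linear <- function(cin, cout, zero_init = FALSE) {
  w <- ag(if (zero_init) matrix(0, cin, cout)
          else matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin,
                      cout), requires = TRUE)
  m <- new_module("linear", params = list(w = w))
  m$w <- w
  m
}

layer_scalar <- function(init = 1) {
  s <- ag(init, requires = TRUE)
  m <- new_module("scalar", params = list(s = s))
  m$s <- s
  m
}

# force every convolution / projection weight in a module tree to zero
# (normalization affines and fusion scalars are left alone); used by the
# closed-form gating tests
zero_conv_weights <- function(mod) {
  if (mod$kind %in% c("conv2d", "conv1d", "linear"))
    for (p in mod$params) p$v <- p$v * 0
  for (ch in mod$children) zero_conv_weights(ch)
  invisible(mod)
}
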