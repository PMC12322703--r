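#' ResNet-AL backbone
#'
#' ResNet34 stage layout (stem: 7x7 stride-2 convolution + 3x3 stride-2
#' max-pool; stages of 3/4/6/3 BasicBlocks at widths 64/128/256/512 with
#' strides 1/2/2/2). Each BasicBlock is
#' `ReLU(identity(x) + ABSM(BN(conv3x3(ReLU(BN(conv3x3(x)))))))` - the
#' background-suppression module sits on the residual branch before the
#' addition, and a 1x1 stride-matched projection carries the identity when
#' the shape changes. When enabled, one LMSM follows each stage. The
#' backbone emits the three-level pyramid (a, b, c) at strides 32/16/8
#' from the outputs of stages 4/3/2.
#'
#' @name backbone
#' @keywords internal
NULL

basic_block_new <- function(cin, cout, stride, cfg) {
  force(cin); force(cout); force(stride)
  ch <- list(conv1 = layer_conv2d(3L, cin, cout, stride = stride, pad = 1L),
             bn1 = layer_bn2d(cout),
             conv2 = layer_conv2d(3L, cout, cout, pad = 1L),
             bn2 = layer_bn2d(cout))
  if (cin != cout || stride != 1L) {
    ch$proj <- layer_conv2d(1L, cin, cout, stride = stride, pad = 0L)
    ch$bnp <- layer_bn2d(cout)
  }
  if (cfg$enable_absm) ch$absm <- absm_new(cout, cfg$absm)
  m <- new_module("basic_block", children = ch)
  m$forward <- function(x, training = TRUE) {
    r <- ch$conv1$forward(x, training)
    r <- ag_relu(ch$bn1$forward(r, training))
    r <- ch$bn2$forward(ch$conv2$forward(r, training), training)
    if (cfg$enable_absm) r <- ch$absm$forward(r, training)
    idt <- if (is.null(ch$proj)) x
           else ch$bnp$forward(ch$proj$forward(x, training), training)
    ag_relu(ag_add(idt, r))
  }
  m
}

backbone_new <- function(cfg) {
  w <- cfg$widths
  ch <- list(stem_conv = layer_conv2d(7L, 3L, w[1], stride = 2L, pad = 3L),
             stem_bn = layer_bn2d(w[1]))
  cin <- w[1]
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks[s])) {
      stride <- if (b == 1L) cfg$strides[s] else 1L
      ch[[sprintf("s%db%d", s, b)]] <-
        basic_block_new(if (b == 1L) cin else w[s], w[s], stride, cfg)
    }
    if (cfg$enable_lmsm)
      ch[[sprintf("lmsm%d", s)]] <- lmsm_new(w[s], cfg$lmsm)
    cin <- w[s]
  }
  m <- new_module("backbone", children = ch)
  m$forward <- function(x, training = TRUE) {
    d <- dim(x$v)
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
      stop("backbone input spatial size must be divisible by 32")
    h <- ag_relu(ch$stem_bn$forward(ch$stem_conv$forward(x, training),
                                    training))
    h <- ag_maxpool(h, 3L, 2L, 1L)
    taps <- list()
    for (s in 1:4) {
      for (b in seq_len(cfg$blocks[s]))
        h <- ch[[sprintf("s%db%d", s, b)]]$forward(h, training)
      if (cfg$enable_lmsm)
        h <- ch[[sprintf("lmsm%d", s)]]$forward(h, training)
      taps[[s]] <- h
    }
    list(a = taps[[4]], b = taps[[3]], c = taps[[2]])
  }
  m
}
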