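# Architecture-module contracts: shapes, normalization, closed-form
# zero-weight behaviour, residual identities, gradient flow.

absm_cfg_ <- list(heads = 4L, compress_kernel = 7L, compress_stride = 2L,
                  profile_kernel = 3L)
lmsm_cfg_ <- list(dilations = 1:4, reduction = 16L, inner_cap = 16L,
                  inner_min = 4L, local_pool = 2L, kernel1d = 3L)

test_that("ABSM preserves shape and normalizes channel weights", {
  set.seed(1)
  absm <- ns_$absm_new(8L, absm_cfg_)
  x <- array(rnorm(10 * 14 * 8 * 2), c(10, 14, 8, 2))
  y <- absm$forward(ns_$ag_const(x), training = FALSE)
  expect_identical(dim(y$v), dim(x))
  w <- absm$channel_weights(ns_$ag_const(x))
  sums <- apply(matrix(w$v, 8, 2), 2, sum)
  expect_equal(sums, c(1, 1), tolerance = 1e-6)
  expect_error(ns_$absm_new(6L, absm_cfg_), "divisible")
})

test_that("ABSM with zeroed convolutions reduces to 0.25 * input", {
  set.seed(2)
  absm <- ns_$absm_new(8L, absm_cfg_)
  ns_$zero_conv_weights(absm)
  x <- array(rnorm(12 * 12 * 8 * 2), c(12, 12, 8, 2))
  y <- absm$forward(ns_$ag_const(x), training = FALSE)
  expect_equal(y$v, 0.25 * x, tolerance = 1e-12)
})

test_that("ABSM gating is bounded by the input magnitude", {
  set.seed(3)
  absm <- ns_$absm_new(8L, absm_cfg_)
  x <- array(rnorm(8 * 8 * 8 * 1), c(8, 8, 8, 1))
  y <- absm$forward(ns_$ag_const(x), training = FALSE)
  w <- absm$channel_weights(ns_$ag_const(x))
  f1 <- x * rep(8 * as.numeric(w$v), each = 64)
  expect_true(max(abs(y$v)) <= max(abs(f1)) + 1e-9)
})

test_that("LMSM is shape-preserving and residual-safe", {
  set.seed(4)
  lm <- ns_$lmsm_new(32L, lmsm_cfg_)
  x <- array(rnorm(6 * 6 * 32), c(6, 6, 32, 1))
  y <- lm$forward(ns_$ag_const(x), training = FALSE)
  expect_identical(dim(y$v), dim(x))
  # zeroed branch weights -> exact identity
  lm0 <- ns_$lmsm_new(32L, lmsm_cfg_)
  ns_$zero_conv_weights(lm0)
  y0 <- lm0$forward(ns_$ag_const(x), training = FALSE)
  expect_equal(y0$v, x, tolerance = 1e-12)
})

test_that("LMSM width arithmetic and dilation geometry", {
  # 512 channels at reduction 16 capped at 16 -> four slices of 4
  expect_equal(ns_$lmsm_inner_width(512L, lmsm_cfg_), 16)
  expect_equal(ns_$lmsm_inner_width(64L, lmsm_cfg_), 4)
  # a dilated 3x3 kernel sees (2d+1) per axis: d = 4 -> 9x9
  d <- 4L
  x <- array(0, c(11, 11, 1, 1))
  x[6, 6, 1, 1] <- 1
  w <- ns_$ag_const(array(1, c(3, 3, 1, 1)))
  y <- ns_$ag_conv2d(ns_$ag_const(x), w, pad = d, dilation = d)
  nz <- which(y$v != 0, arr.ind = TRUE)
  expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1, 2 * d + 1)
  expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1, 2 * d + 1)
})

test_that("WSAF zero-weight case yields 1.5x the first operand", {
  set.seed(5)
  u <- ns_$wsaf_new(8L, 16L, 4L, 400L)
  ns_$zero_conv_weights(u)
  u$children$w2$s$v <- 0
  f01 <- array(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  f01 <- sweep(f01, 3, apply(f01, 3, mean))   # zero mean per channel
  f02 <- array(rnorm(12 * 12 * 16), c(12, 12, 16, 1))
  y <- u$forward(ns_$ag_const(f01), ns_$ag_const(f02), training = FALSE)
  expect_equal(y$v, 1.5 * f01, tolerance = 1e-12)
})

test_that("WSAF aligns mismatched operands to the first operand's shape", {
  set.seed(6)
  u <- ns_$wsaf_new(8L, 4L, 4L, 50L)
  f01 <- array(rnorm(5 * 5 * 8), c(5, 5, 8, 1))
  f02 <- array(rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  y <- u$forward(ns_$ag_const(f01), ns_$ag_const(f02), training = FALSE)
  expect_identical(dim(y$v), dim(f01))
})

test_that("WSAF gate term is live (g = 1 changes the output)", {
  set.seed(7)
  u <- ns_$wsaf_new(8L, 8L, 4L, 64L)
  f01 <- ns_$ag_const(array(rnorm(6 * 6 * 8), c(6, 6, 8, 1)))
  f02 <- ns_$ag_const(array(rnorm(6 * 6 * 8), c(6, 6, 8, 1)))
  y <- u$forward(f01, f02, training = FALSE)
  # rebuilding the fusion with the gate clamped to 1 (z = 2 * F1) must
  # give a different output than the sigmoid gate
  ch <- u$children
  al <- ch$align$forward(ns_$ag_resize(f02, 6, 6), FALSE)
  f1 <- ns_$ag_add(ns_$ag_smul(f01, ch$w1$s), ns_$ag_smul(al, ch$w2$s))
  z1 <- ns_$ag_scale(f1, 2)
  attn <- ns_$ag_mhsa_spatial(z1, ch$wq$w, ch$wk$w, ch$wv$w, ch$wo$w,
                              4L, 64L)
  y_nogate <- ns_$ag_add(z1, attn)
  expect_gt(max(abs(y$v - y_nogate$v)), 1e-6)
})

test_that("PFFM builds five units, shares ab/bc, and matches strides", {
  set.seed(8)
  cfg <- tiny_cfg()
  pf <- ns_$pffm_new(cfg)
  expect_length(pf$children, 5L)
  pyr <- list(a = ns_$ag_const(array(rnorm(2 * 2 * 64), c(2, 2, 64, 1))),
              b = ns_$ag_const(array(rnorm(4 * 4 * 32), c(4, 4, 32, 1))),
              c = ns_$ag_const(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))))
  out <- pf$forward(pyr, training = FALSE)
  expect_identical(dim(out$A$v), c(2L, 2L, 64L, 1L))
  expect_identical(dim(out$B$v), c(4L, 4L, 32L, 1L))
  expect_identical(dim(out$C$v), c(8L, 8L, 16L, 1L))
})

test_that("gradients from all three fused outputs reach the shared units", {
  set.seed(9)
  cfg <- tiny_cfg()
  pf <- ns_$pffm_new(cfg)
  pyr <- list(a = ns_$ag_const(array(rnorm(2 * 2 * 64), c(2, 2, 64, 1))),
              b = ns_$ag_const(array(rnorm(4 * 4 * 32), c(4, 4, 32, 1))),
              c = ns_$ag_const(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))))
  out <- pf$forward(pyr, training = TRUE)
  loss <- ns_$ag_add(ns_$ag_sum(ns_$ag_square(out$A)),
                     ns_$ag_add(ns_$ag_sum(ns_$ag_square(out$B)),
                                ns_$ag_sum(ns_$ag_square(out$C))))
  ns_$ag_backward(loss)
  for (nm in c("u_ab", "u_bc")) {
    ps <- ns_$collect_params(pf$children[[nm]])
    gnorm <- sum(vapply(ps, function(p)
      if (is.null(p$grad)) 0 else sum(abs(p$grad)), numeric(1)))
    expect_gt(gnorm, 0, label = nm)
  }
})

test_that("backbone emits the documented pyramid shapes", {
  set.seed(10)
  cfg <- tiny_cfg("resnet34-d")
  bb <- ns_$backbone_new(cfg)
  x <- ns_$ag_const(array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
  pyr <- bb$forward(x, training = FALSE)
  expect_identical(dim(pyr$a$v), c(2L, 2L, 64L, 1L))   # stride 32
  expect_identical(dim(pyr$b$v), c(4L, 4L, 32L, 1L))   # stride 16
  expect_identical(dim(pyr$c$v), c(8L, 8L, 16L, 1L))   # stride 8
  expect_error(bb$forward(ns_$ag_const(array(0, c(60, 60, 3, 1)))),
               "divisible")
})

test_that("basic block matches standard ResNet shapes with ABSM off/on", {
  set.seed(11)
  cfg <- tiny_cfg("resnet34-d")
  blk <- ns_$basic_block_new(16L, 16L, 1L, cfg)
  x <- ns_$ag_const(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)))
  expect_identical(dim(blk$forward(x, FALSE)$v), c(8L, 8L, 16L, 1L))
  blk2 <- ns_$basic_block_new(16L, 32L, 2L, cfg)
  expect_identical(dim(blk2$forward(x, FALSE)$v), c(4L, 4L, 32L, 1L))
  cfg_a <- tiny_cfg("resnet34-ad")
  blk3 <- ns_$basic_block_new(16L, 16L, 1L, cfg_a)
  expect_identical(dim(blk3$forward(x, FALSE)$v), c(8L, 8L, 16L, 1L))
  expect_true("absm" %in% names(blk3$children))
  expect_false("absm" %in% names(blk$children))
})

test_that("forward pass stays finite over repeated random inputs", {
  set.seed(12)
  m <- alpd_model(tiny_cfg())
  for (s in 1:5) {
    x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
    raw <- ns_$model_forward(m, x, training = FALSE)
    for (lv in raw) {
      expect_true(all(is.finite(lv$box$v)))
      expect_true(all(is.finite(lv$cls$v)))
      expect_true(all(lv$box$v >= 0))   # softplus non-negativity
    }
  }
})

test_that("ablation presets map onto the documented flag chain", {
  flags <- t(vapply(c("resnet34-d", "resnet34-ad", "resnet34-ald",
                      "alpd-net"),
                    function(p) {
                      cfg <- alpd_config(p)
                      c(cfg$enable_absm, cfg$enable_lmsm, cfg$enable_pffm)
                    }, logical(3)))
  expect_equal(unname(flags),
               rbind(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                     c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)))
})
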