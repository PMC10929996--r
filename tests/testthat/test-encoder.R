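# Encoder building blocks: Conv-IN-ReLU contracts, residual identity
# behaviour, backbone stride ladders, and pyramid fusion.

test_that("conv_in_relu output is non-negative and stride-2 halves dims", {
  set.seed(201)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  y <- conv_in_relu(x, out_channels = 4, kernel = 3, stride = 1)
  expect_equal(dim(y), c(16L, 16L, 16L, 4L))
  expect_gte(min(y), 0)
  y2 <- conv_in_relu(x, out_channels = 4, kernel = 3, stride = 2)
  expect_equal(dim(y2)[1:3], c(8L, 8L, 8L))
  expect_error(conv_in_relu(x, 4, kernel = 4), "odd")
  expect_error(conv_in_relu(x, 4, kernel = 3, stride = 3), "stride")
  expect_error(conv_in_relu(array(0, c(2, 2, 2, 1)), 4, kernel = 5),
               "larger than input")
})

test_that("instance normalization standardizes each channel before ReLU", {
  set.seed(202)
  x <- ag_ns("ag_tensor")(array(rnorm(12^3 * 3, mean = 5, sd = 3),
                                c(12, 12, 12, 3)))
  w <- ag_ns("params_conv")(3L, 3L, 4L)
  n <- ag_ns("params_norm")(4L)
  y <- ag_ns("ag_conv3d")(x, w$w, w$b, 1L)
  z <- ag_ns("ag_instance_norm")(y, n$g, n$b)
  zm <- matrix(z$value, ncol = 4)
  expect_lt(max(abs(colMeans(zm))), 1e-6)
  expect_lt(max(abs(apply(zm, 2, sd) - 1)), 1e-3)
})

test_that("residual block reduces to its shortcut when transform is zeroed", {
  set.seed(203)
  x <- array(rnorm(10^3 * 4), c(10, 10, 10, 4))
  p <- ag_ns("params_res_block")(5L, 4L, 4L, 1L)
  p$conv5$w$value[] <- 0; p$conv5$b$value[] <- 0
  p$conv1$w$value[] <- 0; p$conv1$b$value[] <- 0
  y <- residual_block(x, params = p)
  expect_equal(y, x)                       # identity shortcut, exactly
  # same-shape contract for a non-downsampling stage
  p2 <- ag_ns("params_res_block")(5L, 4L, 4L, 1L)
  expect_equal(dim(residual_block(x, params = p2)), dim(x))
})

test_that("gradient flows through the residual shortcut at least as strongly", {
  set.seed(204)
  agt <- ag_ns("ag_tensor"); wt <- ag_ns("ag_with_tape")
  bw <- ag_ns("ag_backward"); s <- ag_ns("ag_sum")
  x1 <- agt(array(rnorm(6^3 * 2), c(6, 6, 6, 2)), requires_grad = TRUE)
  p <- ag_ns("params_res_block")(5L, 2L, 2L, 1L)
  l1 <- wt(s(ag_ns("res_block_forward")(x1, p, 1L))); bw(l1)
  g_res <- x1$grad
  # transform-only path: remove the shortcut by subtracting x
  x2 <- agt(x1$value, requires_grad = TRUE)
  l2 <- wt(s(ag_ns("ag_add")(ag_ns("res_block_forward")(x2, p, 1L),
                             ag_ns("ag_scale")(x2, -1))))
  bw(l2)
  expect_gte(sqrt(sum(g_res^2)), sqrt(sum(x2$grad^2)) * 0.99)
})

test_that("stem raises a single-channel image to base_channels at stride 1", {
  set.seed(205)
  cfg <- tiny_config()
  x <- array(runif(16^3), c(16, 16, 16))
  y <- stem(x, cfg = cfg)
  expect_equal(dim(y), c(16L, 16L, 16L, cfg$base_channels))
  z <- stem(array(0, c(16, 16, 16)), cfg = cfg)
  expect_true(all(is.finite(z)))
})

test_that("doubling base channels roughly quadruples stem parameters", {
  count_stem <- function(bc) {
    set.seed(1)
    cfg <- model_config(patch_size = 16L, base_channels = bc,
                        fpn_channels = 3L * bc, n_heads = 2L)
    p <- ag_ns("params_backbone")(cfg)
    sum(vapply(ag_ns("params_flatten")(p$stem, "s"),
               function(t) length(t$value), numeric(1)))
  }
  r <- count_stem(8L) / count_stem(4L)
  expect_gt(r, 3); expect_lt(r, 4.5)   # conv weights scale ~4x, biases ~2x
})

test_that("backbone stride ladders match the stage arithmetic", {
  set.seed(206)
  cfg <- tiny_config()
  x <- array(runif(32^3), c(32, 32, 32))   # the x2-upsampled 16^3 patch
  maps <- shallow_forward(x, cfg = cfg)
  expect_length(maps, 6L)
  expect_equal(vapply(maps, function(m) m$stride, numeric(1)),
               c(1, 2, 4, 8, 16, 32))
  expect_equal(vapply(maps, function(m) dim(m$x$value)[1], numeric(1)),
               c(32, 16, 8, 4, 2, 1))
  expect_true(all(vapply(maps, function(m) all(is.finite(m$x$value)),
                         logical(1))))
  # deterministic under fixed weights
  p <- ag_ns("params_backbone")(cfg)
  m1 <- shallow_forward(x, params = p, cfg = cfg)
  m2 <- shallow_forward(x, params = p, cfg = cfg)
  expect_identical(m1[[6]]$x$value, m2[[6]]$x$value)
})

test_that("deep backbone groups nine blocks and stops at a coarse floor", {
  set.seed(207)
  cfg <- model_config(patch_size = 96L, base_channels = 4L,
                      fpn_channels = 12L, n_heads = 2L)
  x <- array(runif(48^3), c(48, 48, 48))   # the x2-downsampled 96^3 patch
  maps <- deep_forward(x, cfg = cfg)
  expect_length(maps, 6L)
  coarsest <- dim(maps[[6]]$x$value)[1:3]
  expect_true(all(coarsest >= 3))
  z <- deep_forward(array(0, c(16, 16, 16)), cfg = tiny_config())
  expect_true(all(is.finite(z[[6]]$x$value)))
})

test_that("the deep backbone has more parameters than the shallow one", {
  set.seed(208)
  cfg <- tiny_config()
  np <- function(p) sum(vapply(ag_ns("params_flatten")(p, "p"),
                               function(t) length(t$value), numeric(1)))
  expect_gt(np(ag_ns("params_backbone")(cfg, deep = TRUE)),
            np(ag_ns("params_backbone")(cfg, deep = FALSE)))
})

test_that("pyramid fusion honours the additive fusion rule", {
  set.seed(209)
  cfg <- tiny_config()
  # single-map pyramid: fusion reduces to the 1x1x1 projection alone
  agt <- ag_ns("ag_tensor")
  m <- ag_ns("new_fmap")(agt(array(rnorm(4^3 * cfg$base_channels),
                                   c(4, 4, 4, cfg$base_channels))),
                         "shallow", 1L, 1L)
  pp <- ag_ns("params_fpn")(cfg)
  f1 <- msfpn_fuse(list(shallow = list(m)), pp, cfg)
  direct <- ag_ns("ag_conv3d")(m$x, pp$sh[[1]]$w, pp$sh[[1]]$b, 1L)
  expect_equal(f1$maps[[1]]$x$value, direct$value)
  expect_true(f1$fused)
  # fused dims equal input dims, channels uniform
  x <- array(runif(32^3), c(32, 32, 32))
  sh <- shallow_forward(x, cfg = cfg)
  dp <- deep_forward(array(runif(8^3), c(8, 8, 8)), cfg = cfg)
  fz <- msfpn_fuse(list(shallow = sh, deep = dp), cfg = cfg)
  for (i in seq_along(sh)) {
    expect_equal(dim(fz$maps[[i]]$x$value)[1:3], dim(sh[[i]]$x$value)[1:3])
    expect_equal(dim(fz$maps[[i]]$x$value)[4], cfg$fpn_channels)
  }
  expect_error(msfpn_fuse(list(shallow = list())), "empty")
})

test_that("identity projection with zero coarse input passes features through", {
  set.seed(210)
  cfg <- tiny_config()
  C <- cfg$base_channels
  agt <- ag_ns("ag_tensor")
  # two-scale shallow pyramid; coarse map zero, fine projection = identity
  fine <- ag_ns("new_fmap")(agt(array(rnorm(8^3 * C), c(8, 8, 8, C))),
                            "shallow", 1L, 1L)
  coarse <- ag_ns("new_fmap")(agt(array(0, c(4, 4, 4, 2L * C))),
                              "shallow", 2L, 2L)   # stage-2 width is 2C
  cfg2 <- model_config(patch_size = 16L, base_channels = C,
                       fpn_channels = C, n_heads = 2L)
  pp <- ag_ns("params_fpn")(cfg2)
  pp$sh[[1]]$w$value[] <- 0
  for (c in seq_len(C)) pp$sh[[1]]$w$value[1, 1, 1, c, c] <- 1
  pp$sh[[1]]$b$value[] <- 0
  f <- msfpn_fuse(list(shallow = list(fine, coarse)), pp, cfg2)
  expect_equal(f$maps[[1]]$x$value, fine$x$value)
})

test_that("shape contract holds across valid patch sizes", {
  set.seed(211)
  cfg <- tiny_config()
  for (n in c(16L, 32L)) {
    maps <- shallow_forward(array(runif(n^3), c(n, n, n)), cfg = cfg)
    expect_equal(vapply(maps, function(m) dim(m$x$value)[1], integer(1)),
                 as.integer(pmax(n / 2^(0:5), 1)))
  }
})
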