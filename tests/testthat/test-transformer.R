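# Positional encodings (closed forms), pyramid flattening, deformable
# attention contracts, and DeTrans layer identity behaviour.

test_that("positional encoding satisfies its closed forms", {
  for (C in c(48L, 96L)) {
    for (len in c(1L, 7L, 64L)) {
      tab <- positional_encoding(len, C)
      cpa <- C / 3
      expect_equal(dim(tab), c(len, cpa))
      # pos = 0: sin terms 0, cos terms 1
      expect_equal(tab[1, seq(1, cpa, by = 2)], rep(0, cpa / 2))
      expect_equal(tab[1, seq(2, cpa, by = 2)], rep(1, cpa / 2))
      # Pythagorean identity for every (pos, k)
      s2c2 <- tab[, seq(1, cpa, by = 2), drop = FALSE]^2 +
              tab[, seq(2, cpa, by = 2), drop = FALSE]^2
      expect_lt(max(abs(s2c2 - 1)), 1e-12)
      # k = 0 gives v = 1, so the first column is sin(pos)
      expect_equal(tab[, 1], sin(0:(len - 1)))
      expect_lte(max(tab), 1); expect_gte(min(tab), -1)
    }
  }
  expect_error(positional_encoding(8, 20), "divisible by 6")
})

test_that("distinct axis positions get distinct encodings at practical sizes", {
  tab <- positional_encoding(64L, 48L)
  expect_equal(nrow(unique(round(tab, 9))), 64L)
})

test_that("flattening follows raster order and tags positions per scale", {
  set.seed(301)
  C <- 12L
  agt <- ag_ns("ag_tensor")
  m1 <- ag_ns("new_fmap")(agt(array(rnorm(2 * 2 * 2 * C), c(2, 2, 2, C))),
                          "shallow", 6L, 32L)
  sq <- flatten_with_pos(list(m1))
  expect_equal(nrow(sq$tokens$value), 8L)
  expect_equal(ncol(sq$tokens$value), C)
  # token order is H fastest: token 2 is voxel (2,1,1)
  expect_equal(sq$tokens$value[2, ], m1$x$value[2, 1, 1, ])
  # same (h,w,d) in different scales gets the same positional vector
  m2 <- ag_ns("new_fmap")(agt(array(rnorm(3 * 3 * 3 * C), c(3, 3, 3, C))),
                          "shallow", 5L, 16L)
  sq2 <- flatten_with_pos(list(m2, m1))  # coarsest (m1) first after sorting
  e1 <- sq2$encodings[sq2$scales[[1]]$rows, ]
  e2 <- sq2$encodings[sq2$scales[[2]]$rows, ]
  expect_equal(e1[1, ], e2[1, ])         # both are grid position (0,0,0)
  expect_equal(e1[2, ], e2[2, ])         # both are (1,0,0)
  expect_lte(max(abs(sq2$encodings)), 1)
})

test_that("flatten / reshape_to_volume is an exact inverse pair", {
  set.seed(302)
  C <- 12L
  agt <- ag_ns("ag_tensor")
  m <- ag_ns("new_fmap")(agt(array(rnorm(4 * 3 * 2 * C), c(4, 3, 2, C))),
                         "shallow", 1L, 1L)
  sq <- flatten_with_pos(list(m))
  back <- reshape_to_volume(sq, c(4, 3, 2))
  expect_equal(back$value, m$x$value)
  expect_error(reshape_to_volume(sq, c(4, 4, 2)), "does not match")
  # order sensitivity: permuting tokens changes the reconstruction
  perm <- sq
  perm$tokens <- agt(sq$tokens$value[c(2:1, 3:24), ])
  expect_false(identical(reshape_to_volume(perm, c(4, 3, 2))$value,
                         m$x$value))
})

make_seq <- function(C = 12L, seed = 303) {
  set.seed(seed)
  agt <- ag_ns("ag_tensor")
  maps <- list(
    ag_ns("new_fmap")(agt(array(rnorm(4^3 * C), c(4, 4, 4, C))),
                      "shallow", 4L, 8L),
    ag_ns("new_fmap")(agt(array(rnorm(2^3 * C), c(2, 2, 2, C))),
                      "shallow", 5L, 16L))
  flatten_with_pos(maps)
}

test_that("attention weights are a softmax over scales x points per head", {
  sq <- make_seq()
  cfg <- tiny_config()
  set.seed(304)
  out <- deformable_attention(sq, cfg, return_details = TRUE)
  det <- attr(out$tokens, "details")
  expect_length(det$weights, cfg$n_heads)
  for (wh in det$weights) {
    expect_equal(rowSums(wh), rep(1, nrow(sq$tokens$value)))
    expect_gte(min(wh), 0)
  }
  # linear cost: sampled locations scale linearly with sequence length
  expect_equal(nrow(det$offsets), nrow(sq$tokens$value))
  expect_equal(ncol(det$offsets),
               cfg$n_heads * length(sq$scales) * cfg$n_points * 3L)
})

test_that("zero offsets with uniform weights average value projections", {
  # with offset/weight heads at zero (the initialization), each query
  # averages the value features sampled at its own reference location in
  # every scale
  sq <- make_seq(C = 12L, seed = 305)
  cfg <- tiny_config()
  set.seed(306)
  p <- ag_ns("params_detrans_layer")(12L, cfg$n_heads, length(sq$scales),
                                     cfg$n_points, 24L)
  p$o$w$value[] <- 0
  for (c in 1:12) p$o$w$value[c, c] <- 1   # identity output projection
  out <- ag_ns("deformable_attention_core")(sq$tokens, sq$scales, p,
                                            cfg$n_heads, cfg$n_points)
  # manual expectation: mean over scales of V sampled at the reference
  V <- sq$tokens$value %*% p$v$w$value
  refs <- do.call(rbind, lapply(sq$scales, function(m) m$ref))
  smpl <- function(scale) {
    dims <- sq$scales[[scale]]$dims
    Vg <- array(V[sq$scales[[scale]]$rows, ], c(dims, 12L))
    coords <- sweep(refs, 2, pmax(dims - 1L, 1L), "*")
    ag_ns(".cpp_grid_sample")(Vg, c(dims, 12L), coords)
  }
  expected <- (smpl(1) + smpl(2)) / 2
  expect_equal(out$value, expected, tolerance = 1e-10)
})

test_that("a DeTrans layer with zeroed residual branches is the identity", {
  sq <- make_seq(C = 12L, seed = 307)
  cfg <- tiny_config()
  set.seed(308)
  p <- ag_ns("params_detrans_layer")(12L, cfg$n_heads, length(sq$scales),
                                     cfg$n_points, 24L)
  p$o$w$value[] <- 0; p$o$b$value[] <- 0        # attention branch -> 0
  p$ffn2$w$value[] <- 0; p$ffn2$b$value[] <- 0  # feed-forward branch -> 0
  out <- detrans_layer(sq, cfg, p)
  expect_equal(out$tokens$value, sq$tokens$value)
  # and an entire stack of such layers remains the identity
  ws <- lapply(1:3, function(i) p)
  out3 <- transformer_forward(sq, cfg, ws, add_encodings = FALSE)
  expect_equal(out3$tokens$value, sq$tokens$value)
})

test_that("the transformer stack preserves shape and stays finite", {
  sq <- make_seq(C = 12L, seed = 309)
  cfg <- model_config(patch_size = 16L, base_channels = 4L,
                      fpn_channels = 12L, n_layers = 8L, n_heads = 2L,
                      n_points = 2L, ffn_mult = 2L)
  set.seed(310)
  out <- transformer_forward(sq, cfg)
  expect_equal(dim(out$tokens$value), dim(sq$tokens$value))
  expect_true(all(is.finite(out$tokens$value)))
  # n_layers = 1 equals a single layer call with the same weights
  cfg1 <- tiny_config()
  set.seed(311)
  w1 <- list(ag_ns("params_detrans_layer")(12L, cfg1$n_heads,
                                           length(sq$scales), cfg1$n_points,
                                           24L))
  a <- transformer_forward(sq, cfg1, w1, add_encodings = FALSE)
  b <- detrans_layer(sq, cfg1, w1[[1]])
  expect_equal(a$tokens$value, b$tokens$value)
})

test_that("gradient reaches the first layer of a stacked transformer", {
  sq <- make_seq(C = 12L, seed = 312)
  cfg <- model_config(patch_size = 16L, base_channels = 4L,
                      fpn_channels = 12L, n_layers = 2L, n_heads = 2L,
                      n_points = 2L, ffn_mult = 2L)
  set.seed(313)
  ws <- ag_ns("params_transformer")(cfg)
  ws <- lapply(ws, function(p) {
    p$ffn2 <- ag_ns("params_linear")(24L, 12L)
    p$o <- ag_ns("params_linear")(12L, 12L)   # un-zero the output projection
    p
  })
  wt <- ag_ns("ag_with_tape"); bw <- ag_ns("ag_backward")
  l <- wt({
    out <- transformer_forward(sq, cfg, ws)
    ag_ns("ag_sum")(ag_ns("ag_mul")(out$tokens, out$tokens))
  })
  bw(l)
  g <- ws[[1]]$v$w$grad
  expect_false(is.null(g))
  expect_gt(max(abs(g)), 0)
})
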