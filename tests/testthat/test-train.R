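# Loss closed forms, the training loop contracts (determinism, epoch-zero
# identity, checkpointing), and sliding-window inference.

test_that("loss matches closed forms", {
  set.seed(501)
  tgt <- array(as.integer(runif(4^3) < 0.4), c(4, 4, 4))
  # uniform p = 0.5 (logits 0): BCE = ln 2 per voxel, any mask
  z0 <- array(0, c(4, 4, 4))
  expect_equal(compute_loss(z0, tgt, kind = "bce"), log(2))
  # near-perfect prediction: soft-Dice term -> 0
  zinf <- array(ifelse(tgt == 1L, 40, -40), c(4, 4, 4))
  expect_lt(compute_loss(zinf, tgt, kind = "dice"), 1e-4)
  expect_equal(compute_loss(z0, tgt),
               compute_loss(z0, tgt, "dice") + compute_loss(z0, tgt, "bce"))
  # permutation invariance of the voxel order
  perm <- sample(length(tgt))
  zp <- array(rnorm(length(tgt)), dim(tgt))
  expect_equal(compute_loss(zp, tgt),
               compute_loss(array(zp[perm], dim(tgt)),
                            array(tgt[perm], dim(tgt))))
  expect_error(compute_loss(z0, array(0L, c(2, 2, 2))), "mismatch")
  expect_error(compute_loss(z0, tgt, kind = "huber"), "unknown loss")
})

test_that("epochs = 0 returns the initialization unchanged", {
  cases <- list(small_case(seed = 61, dims = c(16L, 16L, 16L),
                           radii = c(3, 5), spacing = c(3, 3, 3)))
  cfg <- train_config(epochs = 0L, patch_size = 16L, val_fraction = 0,
                      seed = 3L)
  m0 <- coretr_model(tiny_config(), seed = 3L)
  ck <- train(cases, cfg, tiny_config())
  w0 <- ag_ns("params_values")(m0$params)
  expect_equal(ck$weights, w0)
  expect_equal(ck$epoch, 0L)
})

test_that("training is deterministic and the loss decreases", {
  cases <- lapply(61:62, function(s)
    small_case(seed = s, dims = c(16L, 16L, 16L), radii = c(4, 7),
               spacing = c(3, 3, 3)))
  cfg <- train_config(epochs = 3L, patch_size = 16L, val_fraction = 0,
                      patches_per_volume = 2L, augment = NULL, seed = 5L)
  ck1 <- train(cases, cfg, tiny_config())
  ck2 <- train(cases, cfg, tiny_config())
  expect_identical(ck1$history$loss, ck2$history$loss)
  expect_equal(ck1$weights, ck2$weights)
  expect_lt(ck1$history$loss[3], ck1$history$loss[1])
})

test_that("checkpoint save/load restores bit-identical predictions", {
  cases <- list(small_case(seed = 63, dims = c(16L, 16L, 16L),
                           radii = c(4, 6), spacing = c(3, 3, 3)))
  cfg <- train_config(epochs = 1L, patch_size = 16L, val_fraction = 0,
                      patches_per_volume = 2L, augment = NULL, seed = 6L)
  ck <- train(cases, cfg, tiny_config())
  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  p1 <- sliding_window_predict(cases[[1]]$volume, ck)
  p2 <- sliding_window_predict(cases[[1]]$volume, ck2)
  expect_identical(p1$voxels, p2$voxels)
  unlink(f)
})

test_that("a NaN-diverging run aborts with a diagnostic", {
  cases <- list(small_case(seed = 64, dims = c(16L, 16L, 16L),
                           radii = c(4, 6), spacing = c(3, 3, 3)))
  cfg <- train_config(epochs = 1L, initial_lr = 1e6, clip_norm = 0,
                      patch_size = 16L, val_fraction = 0,
                      patches_per_volume = 4L, augment = NULL, seed = 7L)
  expect_error(train(cases, cfg, tiny_config()), "diverged|non-finite")
})

test_that("single-tile sliding window equals one thresholded forward pass", {
  cs <- small_case(seed = 65, dims = c(16L, 16L, 16L), radii = c(4, 6),
                   spacing = c(3, 3, 3))
  m <- coretr_model(tiny_config(), seed = 8L)
  pred <- sliding_window_predict(cs$volume, m, patch = 16L)
  logits <- coretr_forward(m, cs$volume$voxels)
  direct <- (1 / (1 + exp(-logits)) >= 0.5) * 1L
  expect_identical(pred$voxels, array(as.integer(direct), c(16, 16, 16)))
  expect_equal(dim(pred$voxels), dim(cs$volume$voxels))
  expect_equal(pred$spacing, cs$volume$spacing)
})

test_that("overlap averaging is seam-free for a constant-output model", {
  # zero decoder head -> logits identically b, probability constant
  cs <- small_case(seed = 66, dims = c(24L, 24L, 24L), radii = c(4, 6),
                   spacing = c(3, 3, 3))
  m <- coretr_model(tiny_config(), seed = 9L)
  m$params$decoder$head$w$value[] <- 0
  m$params$decoder$head$b$value[] <- 2       # p = sigmoid(2) ~ 0.88
  pred <- sliding_window_predict(cs$volume, m, patch = 16L, overlap = 0.5)
  expect_true(all(pred$voxels == 1L))
  m$params$decoder$head$b$value[] <- -2
  pred2 <- sliding_window_predict(cs$volume, m, patch = 16L, overlap = 0.25)
  expect_true(all(pred2$voxels == 0L))
})

test_that("unnormalized volumes are rejected at inference", {
  ph <- generate_phantom(phantom_spec(dims = c(16, 16, 16),
                                      spacing = c(3, 3, 3),
                                      tumor_radii_mm = c(3, 5), seed = 2))
  m <- coretr_model(tiny_config(), seed = 10L)
  expect_error(sliding_window_predict(ph$volume, m),
               class = "coretr_error_unnormalized")
})

test_that("tiling overlap barely changes an overfit-free prediction", {
  cs <- small_case(seed = 67, dims = c(24L, 24L, 24L), radii = c(5, 7),
                   spacing = c(3, 3, 3))
  m <- coretr_model(tiny_config(), seed = 11L)
  a <- sliding_window_predict(cs$volume, m, patch = 16L, overlap = 0.5)
  b <- sliding_window_predict(cs$volume, m, patch = 16L, overlap = 0.25)
  expect_gt(mean(a$voxels == b$voxels), 0.95)
})
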