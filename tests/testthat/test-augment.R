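# The nine-transform augmentation suite: catalogue contract, identity and
# involution behaviour, closed forms, mask binarity, and geometric
# image/mask correspondence.

make_patch <- function(seed = 1, size = 24L) {
  cs <- small_case(seed = seed, dims = rep(size, 3), spacing = c(2, 2, 2),
                   radii = c(5, 8))
  list(image = cs$volume$voxels, mask = cs$mask$voxels)
}

test_that("the catalogue lists exactly nine transforms in order", {
  cat <- transform_catalog()
  expect_equal(nrow(cat), 9L)
  expect_match(cat$name[1], "rotation")
  expect_equal(cat$name[2:3], c("scaling", "flipping"))
  # one-to-one with the config schema
  cfg <- augment_config()
  expect_setequal(names(cfg$enabled), cat$name)
  expect_true(all(cat$parameter %in% names(cfg)))
})

test_that("zero probability everywhere is the identity", {
  p <- make_patch()
  out <- apply_augmentations(p, augment_config(prob = 0), seed = 1)
  expect_identical(out$image, p$image)
  expect_identical(out$mask, p$mask)
})

test_that("unnormalized input is rejected", {
  p <- make_patch()
  p$image <- p$image * 300 - 100
  expect_error(apply_augmentations(p, augment_config()),
               class = "coretr_error_unnormalized")
})

test_that("flip-only augmentation applied twice restores the input", {
  p <- make_patch()
  cfg <- augment_config(enabled = c(rotation = FALSE, scaling = FALSE,
                                    gaussian_noise = FALSE,
                                    gaussian_blur = FALSE, brightness = FALSE,
                                    contrast = FALSE, low_resolution = FALSE,
                                    gamma = FALSE),
                        prob = c(flipping = 1), flip_axes = 2L)
  once <- apply_augmentations(p, cfg, seed = 42)
  twice <- apply_augmentations(once, cfg, seed = 42)
  expect_identical(twice$image, p$image)
  expect_identical(twice$mask, p$mask)
})

test_that("gamma on a constant image gives the closed form c^gamma", {
  p <- list(image = array(0.4, c(16, 16, 16)),
            mask = array(0L, c(16, 16, 16)))
  cfg <- augment_config(enabled = c(rotation = FALSE, scaling = FALSE,
                                    flipping = FALSE, gaussian_noise = FALSE,
                                    gaussian_blur = FALSE, brightness = FALSE,
                                    contrast = FALSE, low_resolution = FALSE),
                        prob = c(gamma = 1), gamma_range = c(1.3, 1.3))
  out <- apply_augmentations(p, cfg, seed = 1)
  expect_equal(out$image, array(0.4^1.3, c(16, 16, 16)), tolerance = 1e-12)
})

test_that("fixed seed gives bit-identical output with everything enabled", {
  p <- make_patch(seed = 2)
  cfg <- augment_config(prob = 0.8)
  a <- apply_augmentations(p, cfg, seed = 77)
  b <- apply_augmentations(p, cfg, seed = 77)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c2 <- apply_augmentations(p, cfg, seed = 78)
  expect_false(identical(a$image, c2$image))
})

test_that("mask stays binary and output in [0,1] under every transform", {
  p <- make_patch(seed = 3)
  for (nm in transform_catalog()$name) {
    en <- stats::setNames(rep(FALSE, 9), transform_catalog()$name)
    en[nm] <- TRUE
    pr <- stats::setNames(rep(0, 9), transform_catalog()$name)
    pr[nm] <- 1
    out <- apply_augmentations(p, augment_config(enabled = en, prob = pr),
                               seed = 5)
    expect_true(all(out$mask %in% c(0L, 1L)), info = nm)
    expect_gte(min(out$image), 0)
    expect_lte(max(out$image), 1)
    if (transform_catalog()$kind[transform_catalog()$name == nm] ==
        "intensity")
      expect_identical(out$mask, p$mask)
  }
})

test_that("spatial transforms keep image/mask geometry in correspondence", {
  # the tumor is bright (soft tissue ~0.26 normalized) inside dark lung
  # (~0.05); after rotation/scaling the mask must still cover bright voxels
  p <- make_patch(seed = 4, size = 32L)
  cfg <- augment_config(enabled = c(gaussian_noise = FALSE,
                                    gaussian_blur = FALSE, brightness = FALSE,
                                    contrast = FALSE, low_resolution = FALSE,
                                    gamma = FALSE),
                        prob = c(rotation = 1, scaling = 1, flipping = 1))
  for (s in 1:5) {
    out <- apply_augmentations(p, cfg, seed = s)
    if (sum(out$mask) < 20) next
    # erode boundary effects: interior mask voxels must be bright
    inner <- out$mask == 1L & out$image > 0.15
    expect_gt(sum(inner) / sum(out$mask), 0.7)
  }
})
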