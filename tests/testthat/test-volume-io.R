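# NIfTI round-trips, the HU truncation + fixed-range normalization chain,
# spacing resampling, and the seeded patch sampler.

test_that("NIfTI write/read round-trip preserves voxels and spacing", {
  ph <- generate_phantom(phantom_spec(dims = c(20, 18, 12),
                                      spacing = c(1, 1, 3),
                                      tumor_radii_mm = c(2, 3), seed = 3))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  back <- read_volume(f)
  expect_equal(back$voxels, ph$volume$voxels, tolerance = 1e-6)
  expect_equal(back$spacing, c(1, 1, 3))
  expect_false(back$normalized)
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(ph$mask, fm)
  mback <- read_volume(fm, mask = TRUE)
  expect_identical(mback$voxels, ph$mask$voxels)
  unlink(c(f, fm))
})

test_that("read_volume raises distinct classed errors", {
  expect_error(read_volume(tempfile()), class = "coretr_error_missing_file")
  f4 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), class = "coretr_error_not_3d")
  expect_error(read_volume(f4), "expected 3D")
  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  suppressWarnings(
    expect_error(read_volume(bad), class = "coretr_error_bad_header"))
  unlink(c(f4, bad))
})

test_that("truncation clamps exactly at the clip bounds", {
  v <- ct_volume(array(c(-2000, 500, 4000, -1024, 3068, 0), c(6, 1, 1)))
  tr <- truncate_hu(v)
  expect_equal(as.numeric(tr$voxels), c(-1024, 500, 3068, -1024, 3068, 0))
  expect_error(truncate_hu(v, lo = 10, hi = 10), "lo must be < hi")
})

test_that("fixed-range normalization maps bounds to 0/1 and midpoints right", {
  v <- ct_volume(array(c(-1024, 3068, 1022), c(3, 1, 1)))
  nm <- minmax_normalize(truncate_hu(v))
  expect_equal(as.numeric(nm$voxels), c(0, 1, (1022 + 1024) / 4092))
  expect_true(nm$normalized)
  expect_error(minmax_normalize(nm), class = "coretr_error_normalized")
  expect_error(truncate_hu(nm), class = "coretr_error_normalized")
})

test_that("truncate + normalize maps any HU input into [0, 1]", {
  set.seed(4)
  v <- ct_volume(array(stats::rnorm(1000, 0, 2000), c(10, 10, 10)))
  nm <- minmax_normalize(truncate_hu(v))
  expect_gte(min(nm$voxels), 0)
  expect_lte(max(nm$voxels), 1)
  expect_equal(min(nm$voxels), 0)   # some voxels clipped at -1024
  expect_equal(max(nm$voxels), 1)
})

test_that("resampling follows the dimension formula and preserves constants", {
  v <- ct_volume(array(7, c(10, 10, 10)), spacing = c(2, 2, 2))
  r <- resample_uniform(v, c(1, 1, 1), method = "windowed-sinc")
  expect_equal(dim(r$voxels), c(20L, 20L, 20L))
  expect_equal(r$spacing, c(1, 1, 1))
  expect_equal(max(abs(r$voxels - 7)), 0, tolerance = 1e-9)
  # no-op resample is the identity
  same <- resample_uniform(v, c(2, 2, 2))
  expect_identical(same$voxels, v$voxels)
  # anisotropic -> isotropic
  va <- ct_volume(array(stats::rnorm(16 * 16 * 8), c(16, 16, 8)),
                  spacing = c(1, 1, 3))
  ra <- resample_uniform(va, c(1, 1, 1), method = "linear")
  expect_equal(dim(ra$voxels), c(16L, 16L, 24L))
  expect_error(resample_uniform(v, c(0, 1, 1)), "positive")
})

test_that("smooth volumes survive a resample round-trip; masks stay binary", {
  g <- seq(0, 1, length.out = 24)
  sm <- outer(outer(sin(pi * g), cos(pi * g)), g)
  v <- ct_volume(sm * 100, spacing = c(2, 2, 2))
  down <- resample_uniform(v, c(1, 1, 1), method = "windowed-sinc")
  back <- resample_uniform(down, c(2, 2, 2), method = "windowed-sinc")
  core <- 5:20   # interior (boundary handling differs at the edge)
  expect_lt(max(abs(back$voxels[core, core, core] -
                    v$voxels[core, core, core])), 1.5)
  m <- seg_mask(random_mask(c(12, 12, 12), 0.3), spacing = c(2, 2, 2))
  rm_ <- resample_uniform(m, c(1, 1, 1))
  expect_true(all(rm_$voxels %in% c(0L, 1L)))
  expect_s3_class(rm_, "seg_mask")
})

test_that("patch sampler is deterministic, in-bounds, and foreground-biased", {
  cs <- small_case(seed = 5, dims = c(48L, 40L, 36L), spacing = c(2, 2, 2))
  p1 <- crop_random_patches(cs$volume, cs$mask, size = 32, n = 4,
                            fg_fraction = 0.5, seed = 9)
  p2 <- crop_random_patches(cs$volume, cs$mask, size = 32, n = 4,
                            fg_fraction = 0.5, seed = 9)
  expect_equal(length(p1), 4L)
  for (i in 1:4) {
    expect_identical(p1[[i]]$corner, p2[[i]]$corner)
    expect_identical(p1[[i]]$image, p2[[i]]$image)
    expect_equal(dim(p1[[i]]$image), c(32L, 32L, 32L))
    expect_equal(dim(p1[[i]]$mask), c(32L, 32L, 32L))
    d <- dim(cs$volume$voxels) + 2 * p1[[i]]$pad
    expect_true(all(p1[[i]]$corner >= 0L & p1[[i]]$corner + 32L <= d))
  }
  # forced foreground: every patch contains the (single) tumor voxel set
  one <- seg_mask(array(0L, dim(cs$mask$voxels)), cs$mask$spacing)
  one$voxels[20, 20, 20] <- 1L
  pf <- crop_random_patches(cs$volume, one, size = 32, n = 6,
                            fg_fraction = 1, seed = 2)
  for (p in pf) expect_equal(sum(p$mask), 1L)
})

test_that("small volumes are symmetrically zero-padded to the patch size", {
  cs <- small_case(seed = 6, dims = c(20L, 20L, 20L), radii = c(4, 6),
                   spacing = c(2, 2, 2))
  p <- crop_random_patches(cs$volume, cs$mask, size = 32, n = 1, seed = 1)
  expect_equal(dim(p[[1]]$image), c(32L, 32L, 32L))
  expect_true(all(p[[1]]$pad > 0))
  expect_equal(p[[1]]$image[1, 1, 1], 0)   # padded corner is air
})
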