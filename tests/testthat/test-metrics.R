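# Dice and Hausdorff metrics against hand-worked values and brute-force
# oracles.

test_that("dice_score matches hand-enumerated and degenerate cases", {
  m <- array(0L, c(4, 4, 4))
  a <- m; a[1:2, 1:2, 1] <- 1L            # |X| = 4
  b <- m; b[2:3, 1:2, 1] <- 1L            # |Y| = 4, overlap 2
  expect_equal(dice_score(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice_score(a, a), 1)
  disj <- m; disj[4, 4, 4] <- 1L
  expect_equal(dice_score(a, disj), 0)
  expect_equal(dice_score(m, m), 1)       # both empty: perfect agreement
  expect_equal(dice_score(m, a), 0)
  expect_error(dice_score(a, array(0L, c(3, 3, 3))), "shapes differ")
})

test_that("hausdorff distance matches brute force on simple constructions", {
  m <- array(0L, c(9, 9, 9))
  a <- m; a[2, 5, 5] <- 1L
  b <- m; b[5, 5, 5] <- 1L
  expect_equal(hausdorff_distance(a, b), 3)            # 3 voxels apart, 1 mm
  expect_equal(hausdorff_distance(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(hausdorff_distance(a, a), 0)
  expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
})

test_that("hausdorff is NA with a warning for empty masks", {
  m <- array(0L, c(4, 4, 4))
  a <- m; a[1, 1, 1] <- 1L
  expect_warning(r <- hausdorff_distance(a, m), "undefined")
  expect_true(is.na(r))
})

test_that("metrics agree with exhaustive brute-force oracles", {
  set.seed(11)
  for (i in 1:60) {
    dims <- sample(3:9, 3, replace = TRUE)
    p <- random_mask(dims, p = stats::runif(1, 0.05, 0.4))
    g <- random_mask(dims, p = stats::runif(1, 0.05, 0.4))
    sp <- stats::runif(3, 0.5, 3)
    expect_identical(dice_score(p, g), bf_dice(p, g))
    expect_equal(hausdorff_distance(p, g, sp), bf_hausdorff(p, g, sp),
                 tolerance = 1e-12)
    expect_equal(hausdorff_distance(p, g, sp, percentile = 0.95),
                 bf_hausdorff(p, g, sp, percentile = 0.95),
                 tolerance = 1e-12)
  }
})

test_that("dice and HD are invariant under common flips", {
  set.seed(12)
  p <- random_mask(c(7, 6, 5), 0.2)
  g <- random_mask(c(7, 6, 5), 0.2)
  flip1 <- function(m) m[dim(m)[1]:1, , , drop = FALSE]
  expect_equal(dice_score(flip1(p), flip1(g)), dice_score(p, g))
  expect_equal(hausdorff_distance(flip1(p), flip1(g)),
               hausdorff_distance(p, g))
})

test_that("hd >= hd95 and dilation toward the reference never lowers dice", {
  set.seed(13)
  dims <- c(20, 20, 20)
  centre <- c(10, 10, 10)
  sphere <- function(r) {
    idx <- arrayInd(seq_len(prod(dims)), dims)
    m <- array(0L, dims)
    m[sqrt(colSums((t(idx) - centre)^2)) <= r] <- 1L
    m
  }
  gt <- sphere(7)
  prev <- -Inf
  for (r in 3:7) {
    d <- dice_score(sphere(r), gt)
    expect_gte(d, prev)
    prev <- d
  }
  p <- sphere(4)
  expect_gte(hausdorff_distance(p, gt),
             hausdorff_distance(p, gt, percentile = 0.95))
})

test_that("split_and_score classifies and reports per-lesion metrics", {
  dims <- c(24, 24, 24)
  gt <- array(0L, dims)
  gt[3:6, 3:6, 3:6] <- 1L
  single <- split_and_score(gt, gt)
  expect_equal(single$category, "single")
  expect_equal(single$n_components_gt, 1L)
  expect_null(single$per_lesion)
  expect_equal(single$dice, 1)

  gt[15:18, 15:18, 15:18] <- 1L
  gt[3:5, 18:20, 3:5] <- 1L
  pred <- gt
  pred[3, 3, 3] <- 0L                      # perturb one lesion slightly
  r <- split_and_score(pred, gt)
  expect_equal(r$category, "multiple")
  expect_equal(r$n_components_gt, 3L)
  expect_equal(nrow(r$per_lesion), 3L)
  expect_true(all(r$per_lesion$dice > 0.9))
})

test_that("global dice decomposes over well-separated lesions", {
  dims <- c(30, 30, 30)
  gt <- array(0L, dims); pred <- array(0L, dims)
  gt[2:5, 2:5, 2:5] <- 1L;    pred[3:6, 2:5, 2:5] <- 1L
  gt[20:25, 20:25, 20:25] <- 1L; pred[20:24, 20:25, 20:25] <- 1L
  r <- split_and_score(pred, gt)
  pl <- r$per_lesion
  inter <- sapply(seq_len(nrow(pl)), function(i)
    (pl$dice[i] * (pl$gt_voxels[i] + pl$pred_voxels[i])) / 2)
  expect_equal(r$dice,
               2 * sum(inter) / (sum(pl$gt_voxels) + sum(pl$pred_voxels)))
})

test_that("connected_components uses 6-connectivity", {
  m <- array(0L, c(4, 4, 4))
  m[1, 1, 1] <- 1L
  m[2, 2, 1] <- 1L                         # diagonal: separate component
  expect_equal(max(connected_components(m)), 2L)
  m[2, 1, 1] <- 1L                         # face-connects the two
  expect_equal(max(connected_components(m)), 1L)
})
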