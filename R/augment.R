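# Training-time augmentation: the nine stochastic transforms applied to
# image/mask patch pairs. Spatial transforms (rotation, scaling, flipping)
# act identically on image and mask (mask via nearest-neighbour, so it stays
# binary); intensity transforms (noise, blur, brightness, contrast,
# low-resolution simulation, gamma) touch the image only. Spatial transforms
# run first so injected noise is never interpolated.

aug_transform_names <- c("rotation", "scaling", "flipping", "gaussian_noise",
                         "gaussian_blur", "brightness", "contrast",
                         "low_resolution", "gamma")

#' Catalogue of the augmentation transforms
#'
#' @return tibble with one row per transform, in application order within
#'   their spatial/intensity groups: name, kind, and the
#'   [augment_config()] field holding its parameters.
#' @export
transform_catalog <- function() {
  tibble::tibble(
    name = aug_transform_names,
    kind = c("spatial", "spatial", "spatial", "intensity", "intensity",
             "intensity", "intensity", "intensity", "intensity"),
    parameter = c("rotation_deg", "scale_range", "flip_axes", "noise_sd",
                  "blur_sigma", "brightness_delta", "contrast_range",
                  "lowres_factor", "gamma_range"))
}

#' Augmentation configuration
#'
#' Each of the nine transforms has an enable flag, a trigger probability, and
#' a parameter range. Magnitude defaults follow common volumetric
#' segmentation practice; all are configurable (and togglable one-by-one for
#' ablations).
#'
#' @param enabled named logical vector (or single logical) enabling
#'   transforms.
#' @param prob named numeric vector (or single numeric) of per-transform
#'   trigger probabilities in `[0, 1]`.
#' @param rotation_deg rotation angle range, degrees, about a random
#'   grid-plane axis.
#' @param scale_range isotropic zoom factor range.
#' @param flip_axes axes eligible for mirroring.
#' @param noise_sd additive Gaussian noise sd range (of the `[0, 1]` range).
#' @param blur_sigma Gaussian blur sigma range, voxels.
#' @param brightness_delta additive intensity shift range.
#' @param contrast_range multiplicative contrast factor range (about the
#'   mean).
#' @param lowres_factor downsampling factor range for low-resolution
#'   simulation.
#' @param gamma_range gamma-transform exponent range.
#' @export
augment_config <- function(enabled = TRUE,
                           prob = c(rotation = 0.2, scaling = 0.2,
                                    flipping = 0.5, gaussian_noise = 0.1,
                                    gaussian_blur = 0.2, brightness = 0.15,
                                    contrast = 0.15, low_resolution = 0.25,
                                    gamma = 0.3),
                           rotation_deg = c(-30, 30),
                           scale_range = c(0.85, 1.25),
                           flip_axes = 1:3,
                           noise_sd = c(0.01, 0.1),
                           blur_sigma = c(0.5, 1.5),
                           brightness_delta = c(-0.1, 0.1),
                           contrast_range = c(0.75, 1.25),
                           lowres_factor = c(1, 2),
                           gamma_range = c(0.7, 1.5)) {
  en <- stats::setNames(rep(TRUE, 9L), aug_transform_names)
  if (length(enabled) == 1L && is.null(names(enabled))) en[] <- enabled
  else en[names(enabled)] <- enabled
  pr <- stats::setNames(rep(0.2, 9L), aug_transform_names)
  if (length(prob) == 1L && is.null(names(prob))) pr[] <- prob
  else pr[names(prob)] <- prob
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  structure(list(enabled = en, prob = pr, rotation_deg = rotation_deg,
                 scale_range = scale_range, flip_axes = flip_axes,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 brightness_delta = brightness_delta,
                 contrast_range = contrast_range,
                 lowres_factor = lowres_factor, gamma_range = gamma_range),
            class = "augment_config")
}

fires <- function(cfg, name) {
  cfg$enabled[[name]] && stats::runif(1) < cfg$prob[[name]]
}

# affine resample about the grid centre: out(p) = in(A (p - c) + c)
affine_resample <- function(arr, A, method, fill = 0) {
  d <- dim(arr)
  ctr <- (d - 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d) - 1
  src <- sweep(sweep(idx, 2L, ctr, "-") %*% t(A), 2L, ctr, "+")
  out <- .cpp_sample_points(arr * 1.0, d, src, method, fill)
  array(out, d)
}

rot_matrix <- function(plane, theta) {
  R <- diag(3)
  i <- plane[1]; j <- plane[2]
  R[i, i] <- cos(theta); R[j, j] <- cos(theta)
  R[i, j] <- -sin(theta); R[j, i] <- sin(theta)
  R
}

gauss_blur <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, pmin(n, i + seq(-r, r)))
      for (t in seq_along(j)) W[i, j[t]] <- W[i, j[t]] + k[t]
    }
    W <- W / rowSums(W)
    arr <- apply_axis(arr, W, ax)
  }
  arr
}

#' Apply the augmentation pipeline to a patch
#'
#' Spatial transforms first (applied to image and mask alike), then
#' intensity transforms (image only); the image is clipped back to `[0, 1]`
#' at the end. Deterministic for a fixed seed.
#'
#' @param patch a `coretr_patch` (from [crop_random_patches()]) or a list
#'   with `image` (normalized to `[0, 1]`) and `mask`.
#' @param cfg an [augment_config()].
#' @param seed optional seed.
#' @return the transformed patch.
#' @export
apply_augmentations <- function(patch, cfg = augment_config(), seed = NULL) {
  img <- patch$image; msk <- patch$mask
  if (min(img) < 0 || max(img) > 1)
    coretr_error("coretr_error_unnormalized",
                 "patch image must be normalized to [0, 1]")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d <- dim(img)

  if (fires(cfg, "rotation")) {
    plane <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[sample.int(3L, 1L)]]
    theta <- stats::runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2]) *
      pi / 180
    A <- rot_matrix(plane, -theta)   # inverse map
    img <- affine_resample(img, A, "linear", 0)
    msk <- affine_resample(msk, A, "nearest", 0)
  }
  if (fires(cfg, "scaling")) {
    f <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    A <- diag(3) / f
    img <- affine_resample(img, A, "linear", 0)
    msk <- affine_resample(msk, A, "nearest", 0)
  }
  if (fires(cfg, "flipping")) {
    for (ax in cfg$flip_axes) {
      if (stats::runif(1) < 0.5) {
        idx <- rev(seq_len(d[ax]))
        if (ax == 1L) { img <- img[idx, , , drop = FALSE]; msk <- msk[idx, , , drop = FALSE] }
        if (ax == 2L) { img <- img[, idx, , drop = FALSE]; msk <- msk[, idx, , drop = FALSE] }
        if (ax == 3L) { img <- img[, , idx, drop = FALSE]; msk <- msk[, , idx, drop = FALSE] }
      }
    }
  }
  if (fires(cfg, "gaussian_noise")) {
    sd <- stats::runif(1, cfg$noise_sd[1], cfg$noise_sd[2])
    img <- img + array(stats::rnorm(prod(d), sd = sd), d)
  }
  if (fires(cfg, "gaussian_blur")) {
    img <- gauss_blur(img, stats::runif(1, cfg$blur_sigma[1],
                                        cfg$blur_sigma[2]))
  }
  if (fires(cfg, "brightness")) {
    img <- img + stats::runif(1, cfg$brightness_delta[1],
                              cfg$brightness_delta[2])
  }
  if (fires(cfg, "contrast")) {
    f <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    img <- (img - mean(img)) * f + mean(img)
  }
  if (fires(cfg, "low_resolution")) {
    f <- stats::runif(1, cfg$lowres_factor[1], cfg$lowres_factor[2])
    if (f > 1) {
      small <- pmax(1L, as.integer(round(d / f)))
      a4 <- array(img, c(d, 1L))
      dn <- .cpp_trilinear_resize(a4, c(d, 1L), c(small, 1L))
      up <- .cpp_trilinear_resize(dn, c(small, 1L), c(d, 1L))
      img <- array(up, d)
    }
  }
  if (fires(cfg, "gamma")) {
    g <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
    img <- pmax(img, 0)^g
  }
  img <- pmin(pmax(img, 0), 1)
  storage.mode(msk) <- "integer"
  patch$image <- img
  patch$mask <- msk
  patch
}
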