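# Synthetic lung-CT phantoms: a soft-tissue body ellipsoid containing two
# low-attenuation lung regions, with 1-3 ellipsoidal tumors placed fully
# inside the lungs. The ground-truth mask is built geometrically (the exact
# union of the tumor ellipsoids), so it is invariant to the additive noise
# field, and the analytic ellipsoid volume provides an oracle for the
# evaluation metrics.

#' Phantom specification
#'
#' @param dims voxel grid dimensions.
#' @param spacing voxel spacing in mm (slice thickness commonly 1-3 mm).
#' @param n_tumors number of tumors (1-3).
#' @param tumor_radii_mm range of tumor semi-axis lengths in mm; the spanned
#'   volumes cover sub-cc nodules through bulky disease.
#' @param tumor_hu HU range of tumor tissue (soft tissue, 0-100 by default).
#' @param background_hu HU of aerated lung (about -800).
#' @param body_hu HU of chest-wall soft tissue (about 40).
#' @param noise_sd standard deviation of additive Gaussian noise, HU.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @export
phantom_spec <- function(dims = c(96L, 96L, 64L),
                         spacing = c(1, 1, 3),
                         n_tumors = 1L,
                         tumor_radii_mm = c(4, 20),
                         tumor_hu = c(0, 100),
                         background_hu = -800,
                         body_hu = 40,
                         noise_sd = 10,
                         seed = 1L) {
  stopifnot(n_tumors >= 1L, all(tumor_radii_mm > 0), all(dims >= 1L),
            all(spacing > 0))
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 n_tumors = as.integer(n_tumors),
                 tumor_radii_mm = as.numeric(tumor_radii_mm),
                 tumor_hu = as.numeric(tumor_hu),
                 background_hu = background_hu, body_hu = body_hu,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipsoid membership on the voxel-centre grid, physical coordinates
ellipsoid_mask <- function(dims, spacing, centre, radii) {
  x <- ((seq_len(dims[1]) - 1) * spacing[1] - centre[1]) / radii[1]
  y <- ((seq_len(dims[2]) - 1) * spacing[2] - centre[2]) / radii[2]
  z <- ((seq_len(dims[3]) - 1) * spacing[3] - centre[3]) / radii[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

#' Generate one synthetic lung-CT phantom
#'
#' Builds an HU-valued volume with a body ellipsoid (`body_hu`), two
#' lung ellipsoids (`background_hu`), and `n_tumors` non-overlapping tumor
#' ellipsoids (uniform HU drawn from `tumor_hu`) placed fully inside a lung;
#' Gaussian noise of sd `noise_sd` is then added to the image only. The mask
#' is the exact geometric union of the tumor ellipsoids.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a `ct_volume`), `mask` (a `seg_mask`), and
#'   `tumors` (a tibble: centre, radii, HU, analytic volume in cc).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  dims <- spec$dims; sp <- spec$spacing
  extent <- (dims - 1) * sp
  ctr <- extent / 2

  vol <- array(-1000, dims)                       # air
  body_r <- extent * c(0.48, 0.48, 0.55)
  body <- ellipsoid_mask(dims, sp, ctr, body_r)
  vol[body] <- spec$body_hu

  lung_r <- extent * c(0.20, 0.32, 0.40)
  lung_c1 <- ctr + c(-0.22, 0, 0) * extent
  lung_c2 <- ctr + c(+0.22, 0, 0) * extent
  lungs <- ellipsoid_mask(dims, sp, lung_c1, lung_r) |
           ellipsoid_mask(dims, sp, lung_c2, lung_r)
  vol[lungs] <- spec$background_hu

  mask <- array(FALSE, dims)
  placed <- list()
  tum <- vector("list", spec$n_tumors)
  for (t in seq_len(spec$n_tumors)) {
    ok <- FALSE
    # radii are drawn from the requested range, capped per axis at what the
    # lung ellipsoid can geometrically contain; infeasible even at the
    # minimum radius (joint support condition) is an error
    r_hi <- pmin(max(spec$tumor_radii_mm), 0.95 * lung_r)
    if (any(r_hi < spec$tumor_radii_mm[1]) ||
        sum((spec$tumor_radii_mm[1] / lung_r)^2) > 1)
      stop("could not place tumor ", t,
           " inside the lung region; reduce radii or n_tumors")
    for (try in seq_len(500L)) {
      r <- stats::runif(3, spec$tumor_radii_mm[1], r_hi)
      lc <- if (stats::runif(1) < 0.5) lung_c1 else lung_c2
      # sample a centre such that the tumor ellipsoid fits inside the lung
      # ellipsoid (conservative per-axis support check)
      margin <- 1 - (r / lung_r)
      if (any(margin <= 0)) next
      u <- stats::runif(3, -1, 1)
      u <- u / max(1, sqrt(sum(u^2)))
      cand <- lc + u * margin * lung_r * 0.95
      if (sum(((abs(cand - lc) + r) / lung_r)^2) > 1) next
      clash <- any(vapply(placed, function(pl)
        sqrt(sum((pl$c - cand)^2)) < max(pl$r) + max(r), logical(1)))
      if (clash) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place tumor ", t,
           " inside the lung region; reduce radii or n_tumors")
    hu <- stats::runif(1, spec$tumor_hu[1], max(spec$tumor_hu))
    em <- ellipsoid_mask(dims, sp, cand, r)
    vol[em] <- hu
    mask <- mask | em
    placed[[t]] <- list(c = cand, r = r)
    tum[[t]] <- tibble::tibble(tumor = t,
                               cx = cand[1], cy = cand[2], cz = cand[3],
                               rx = r[1], ry = r[2], rz = r[3], hu = hu,
                               volume_cc = 4 / 3 * pi * prod(r) / 1000)
  }
  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(dims), sd = spec$noise_sd), dims)

  list(volume = ct_volume(vol, sp),
       mask = seg_mask(mask * 1L, sp),
       tumors = do.call(rbind, tum))
}

#' Generate a reproducible phantom dataset
#'
#' Draws `n_cases` phantom specifications from the supplied ranges (seeded),
#' alternating deterministically through tumor counts so both single- and
#' multiple-tumor cases are always represented.
#'
#' @param n_cases number of cases (>= 1).
#' @param spec_ranges list of ranges overriding [phantom_spec()] defaults:
#'   `dims`, `spacing_z` (slice-thickness range), `n_tumors` (set of counts),
#'   `tumor_radii_mm`, `noise_sd`.
#' @param seed integer seed.
#' @return list of cases, each as returned by [generate_phantom()] plus the
#'   drawn `spec`.
#' @export
phantom_dataset <- function(n_cases, spec_ranges = list(), seed = 1L) {
  stopifnot(n_cases >= 1L)
  rg <- utils::modifyList(
    list(dims = c(96L, 96L, 64L), spacing_xy = c(1, 1), spacing_z = c(1, 3),
         n_tumors = 1:3, tumor_radii_mm = c(3, 25), noise_sd = c(5, 15)),
    spec_ranges)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    sp <- phantom_spec(
      dims = rg$dims,
      spacing = c(rg$spacing_xy, stats::runif(1, rg$spacing_z[1],
                                              max(rg$spacing_z))),
      n_tumors = rg$n_tumors[1L + (i - 1L) %% length(rg$n_tumors)],
      tumor_radii_mm = rg$tumor_radii_mm,
      noise_sd = stats::runif(1, rg$noise_sd[1], max(rg$noise_sd)),
      seed = sample.int(.Machine$integer.max, 1L))
    out <- c(generate_phantom(sp),
             list(spec = sp, case_id = sprintf("case%03d", i)))
    attr(out$volume, "case_id") <- out$case_id
    out
  })
}
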