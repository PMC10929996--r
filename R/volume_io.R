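# CT volume / segmentation mask containers, NIfTI I/O, and the preprocessing
# chain: HU truncation, fixed-range min-max normalization, resampling to
# uniform spacing, and seeded random patch extraction.

coretr_error <- function(class, msg) {
  stop(structure(class = c(class, "coretr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' CT volume container
#'
#' A 3D scalar grid with physical metadata: voxel values (Hounsfield units
#' before normalization, `[0, 1]` after), per-axis spacing in mm, and the
#' physical coordinate of voxel (0, 0, 0).
#'
#' @param voxels numeric 3D array.
#' @param spacing positive length-3 numeric (mm).
#' @param origin length-3 numeric (mm).
#' @param normalized has min-max normalization been applied?
#' @return a `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      normalized = FALSE) {
  if (length(dim(voxels)) != 3L)
    coretr_error("coretr_error_not_3d", "expected 3D volume")
  if (any(spacing <= 0)) stop("spacing components must be strictly positive")
  if (normalized && (min(voxels) < 0 || max(voxels) > 1))
    stop("normalized volume must have values in [0, 1]")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' Segmentation mask container
#'
#' Binary 3D grid geometrically aligned to its paired [ct_volume()].
#'
#' @param voxels 3D array with values in `{0, 1}`.
#' @inheritParams ct_volume
#' @export
seg_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    coretr_error("coretr_error_not_3d", "expected 3D mask")
  v <- as.integer(round(voxels))
  if (!all(voxels %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  dim(v) <- dim(voxels)
  structure(list(voxels = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "seg_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, ", if (x$normalized) "normalized [0,1]" else
        sprintf("HU range [%.0f, %.0f]", min(x$voxels), max(x$voxels)),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, ", sum(x$voxels), " foreground (",
      signif(100 * mean(x$voxels), 3), "%)\n", sep = "")
  invisible(x)
}

#' Read a CT volume (or mask) from NIfTI
#'
#' Populates voxels, spacing, and origin from the header; the orientation is
#' normalized to RAS when the header carries a usable transform. Raises
#' classed errors: `coretr_error_missing_file`, `coretr_error_bad_header`,
#' `coretr_error_not_3d`.
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3D scalar image.
#' @param mask read as a [seg_mask()] instead of a [ct_volume()].
#' @return a `ct_volume` (or `seg_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    coretr_error("coretr_error_missing_file", paste0("file not found: ", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    coretr_error("coretr_error_bad_header",
                                 paste0("unreadable NIfTI header: ",
                                        conditionMessage(e))))
  nd <- length(dim(img))
  if (nd != 3L)
    coretr_error("coretr_error_not_3d",
                 paste0("expected 3D volume, got ", nd, "D"))
  img <- tryCatch({
    if (!identical(RNifti::orientation(img), "RAS"))
      RNifti::orientation(img) <- "RAS"
    img
  }, error = function(e) img)
  spacing <- attr(img, "pixdim")[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  vox <- array(as.numeric(img), dim(img))
  if (mask) seg_mask(vox, spacing, origin)
  else ct_volume(vox, spacing, origin, normalized = FALSE)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a `ct_volume` or `seg_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("ct_volume", "seg_mask")))
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(array(as.numeric(vol$voxels), dim(vol$voxels)))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Truncate Hounsfield units
#'
#' Clamps every voxel into `[lo, hi]` (defaults to the CT-relevant range
#' `[-1024, 3068]` covering air through dense bone/metal).
#'
#' @param vol a `ct_volume` (not yet normalized).
#' @param lo,hi clip bounds in HU.
#' @export
truncate_hu <- function(vol, lo = -1024, hi = 3068) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$normalized)
    coretr_error("coretr_error_normalized",
                 "volume is already normalized; truncation applies to HU")
  if (lo >= hi) stop("lo must be < hi")
  vol$voxels[] <- pmin(pmax(vol$voxels, lo), hi)
  vol
}

#' Fixed-range min-max normalization
#'
#' Maps `[lo, hi]` linearly onto `[0, 1]` using the *fixed* clip bounds (not
#' the per-volume min/max), so a given HU value means the same thing in every
#' scan. Apply [truncate_hu()] with the same bounds first; out-of-range
#' values are clamped defensively.
#'
#' @inheritParams truncate_hu
#' @export
minmax_normalize <- function(vol, lo = -1024, hi = 3068) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$normalized)
    coretr_error("coretr_error_normalized", "volume is already normalized")
  v <- (vol$voxels - lo) / (hi - lo)
  vol$voxels[] <- pmin(pmax(v, 0), 1)
  vol$normalized <- TRUE
  vol
}

# separable resampling weights for one axis
resample_weights <- function(n_in, n_out, sp_in, sp_out, method) {
  scale <- sp_out / sp_in      # input cells per output cell
  # output voxel centre i maps to input index coordinate:
  x <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in - 0.5
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    j <- pmin(pmax(round(x), 0), n_in - 1)
    W[cbind(seq_len(n_out), j + 1)] <- 1
    return(W)
  }
  # anti-aliasing: widen the kernel by the minification factor
  s <- max(1, scale)
  radius <- if (method == "linear") 1 else 3
  for (i in seq_len(n_out)) {
    lo <- max(0, floor(x[i] - radius * s))
    hi <- min(n_in - 1, ceiling(x[i] + radius * s))
    j <- lo:hi
    t <- (j - x[i]) / s
    w <- if (method == "linear") pmax(0, 1 - abs(t))
         else {
           # Lanczos-3 windowed sinc
           w0 <- ifelse(abs(t) < 1e-12, 1,
                        sin(pi * t) / (pi * t) * sin(pi * t / 3) / (pi * t / 3))
           w0[abs(t) >= 3] <- 0
           w0
         }
    if (sum(w) == 0) { w <- rep(0, length(j)); w[which.min(abs(t))] <- 1 }
    W[i, j + 1] <- w / sum(w)
  }
  W
}

apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, d[axis], prod(d[-axis]))
  r <- W %*% m
  out <- array(r, c(nrow(W), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Resample to uniform voxel spacing
#'
#' Separable resampling of a volume onto a new voxel grid whose spacing is
#' `target_spacing`, preserving the physical extent: the output dimension per
#' axis is `round(dim * spacing / target_spacing)`. Interpolation kernels:
#' `"windowed-sinc"` (Lanczos-3, the default for images), `"linear"`, and
#' `"nearest"` (forced for masks so binarity is preserved). Kernels are
#' widened when minifying (anti-aliasing) and renormalized, so constant
#' volumes stay constant.
#'
#' @param vol a `ct_volume` or `seg_mask`.
#' @param target_spacing length-3 positive numeric, mm.
#' @param method `"windowed-sinc"`, `"linear"`, or `"nearest"`.
#' @export
resample_uniform <- function(vol, target_spacing = c(1, 1, 1),
                             method = c("windowed-sinc", "linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, c("ct_volume", "seg_mask")))
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  is_mask <- inherits(vol, "seg_mask")
  if (is_mask) method <- "nearest"
  d <- dim(vol$voxels)
  n_out <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  if (all(n_out == d) && all(abs(vol$spacing - target_spacing) < 1e-12))
    return(vol)
  arr <- vol$voxels * 1.0
  for (ax in 1:3) {
    if (n_out[ax] == d[ax] && abs(vol$spacing[ax] - target_spacing[ax]) < 1e-12)
      next
    W <- resample_weights(d[ax], n_out[ax], vol$spacing[ax],
                          target_spacing[ax], method)
    arr <- apply_axis(arr, W, ax)
    d[ax] <- n_out[ax]
  }
  if (is_mask) seg_mask(round(arr), target_spacing, vol$origin)
  else ct_volume(arr, target_spacing, vol$origin, normalized = vol$normalized)
}

#' Random patch extraction
#'
#' Draws `n` aligned image/mask patches of edge length `size`. With
#' probability `fg_fraction` a patch is centred on a randomly chosen
#' foreground voxel (tumours occupy a tiny fraction of a chest volume, so
#' unbiased sampling would starve the loss of foreground); otherwise the
#' corner is uniform. Volumes smaller than `size` along an axis are
#' symmetrically zero-padded first (0 is air after normalization).
#'
#' @param vol a normalized `ct_volume`.
#' @param mask the aligned `seg_mask`.
#' @param size patch edge length in voxels.
#' @param n number of patches.
#' @param fg_fraction probability of foreground-centred sampling.
#' @param seed optional seed for reproducible draws.
#' @return list of `coretr_patch` objects: `image`, `mask`, `corner`
#'   (0-based, in the padded grid), `pad` (per-axis low-side padding),
#'   `source`.
#' @export
crop_random_patches <- function(vol, mask, size = 96L, n = 4L,
                                fg_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "seg_mask"))
  if (!all(dim(vol$voxels) == dim(mask$voxels)))
    stop("volume and mask dimensions differ")
  if (length(vol$voxels) == 0L) stop("empty volume")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  img <- vol$voxels
  msk <- mask$voxels
  d <- dim(img)
  pad_lo <- pmax(0L, (size - d + 1L) %/% 2L)
  pad_hi <- pmax(0L, size - d - pad_lo)
  if (any(pad_lo > 0L | pad_hi > 0L)) {
    nd <- d + pad_lo + pad_hi
    im2 <- array(0, nd); mk2 <- array(0L, nd)
    im2[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
        pad_lo[3] + seq_len(d[3])] <- img
    mk2[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
        pad_lo[3] + seq_len(d[3])] <- msk
    img <- im2; msk <- mk2; d <- nd
  }
  fg <- which(msk == 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (length(fg) > 0L && stats::runif(1) < fg_fraction) {
      ctr <- arrayInd(fg[sample.int(length(fg), 1L)], d) - 1L
      corner <- pmin(pmax(ctr - size %/% 2L, 0L), d - size)
    } else {
      corner <- vapply(d - size, function(m) sample.int(m + 1L, 1L) - 1L,
                       integer(1))
    }
    sel <- lapply(1:3, function(a) corner[a] + seq_len(size))
    out[[i]] <- structure(
      list(image = img[sel[[1]], sel[[2]], sel[[3]]],
           mask = msk[sel[[1]], sel[[2]], sel[[3]]],
           corner = as.integer(corner), pad = as.integer(pad_lo),
           source = attr(vol, "case_id") %||% NA_character_),
      class = "coretr_patch")
  }
  out
}
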