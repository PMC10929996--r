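# The dual-resolution encoder: a shallow backbone on the 2x-upsampled patch,
# a deep backbone on the 2x-downsampled patch, and the multi-scale feature
# pyramid (Ms-FPN) that fuses them to a common channel width.

new_fmap <- function(x, level, scale, stride) {
  structure(list(x = x, level = level, scale = scale, stride = stride,
                 channels = dim(x$value)[4]),
            class = "coretr_fmap")
}

fmap_size <- function(m) dim(m$x$value)[1:3]

params_backbone <- function(cfg, deep = FALSE) {
  ch <- stage_channels(cfg)
  k0 <- cfg$stem_kernels
  stem <- vector("list", length(k0))
  cin <- cfg$in_channels
  for (i in seq_along(k0)) {
    stem[[i]] <- params_cir(k0[i], cin, cfg$base_channels)
    cin <- cfg$base_channels
  }
  if (!deep) {
    stages <- vector("list", cfg$shallow_stages)
    cin <- cfg$base_channels
    for (s in seq_len(cfg$shallow_stages)) {
      stride <- if (s == 1L) 1L else 2L
      stages[[s]] <- params_res_block(cfg$res_kernel, cin, ch[s], stride)
      cin <- ch[s]
    }
    list(stem = stem, stages = stages)
  } else {
    groups <- vector("list", length(cfg$deep_grouping))
    cin <- cfg$base_channels
    for (g in seq_along(cfg$deep_grouping)) {
      nb <- cfg$deep_grouping[g]
      blocks <- vector("list", nb)
      for (b in seq_len(nb)) {
        stride <- if (b == 1L && g > 1L) 2L else 1L
        blocks[[b]] <- params_res_block(cfg$res_kernel, cin, ch[g], stride)
        cin <- ch[g]
      }
      groups[[g]] <- blocks
    }
    list(stem = stem, groups = groups)
  }
}

stem_forward <- function(x, p, cfg) {
  for (i in seq_along(p)) {
    x <- cir_forward(x, p[[i]], 1L)
  }
  x
}

#' Stem of a backbone
#'
#' Five Conv-IN-ReLU layers (kernels 3, 1, 3, 1, 3 by default): the first
#' block raises the single-channel image to `base_channels`, and the
#' 1^3-then-3^3 pairs refine it at unchanged resolution (stride 1 throughout).
#'
#' @param input single-channel normalized image, `(H, W, D)` or `(H, W, D, 1)`.
#' @param params optional parameter set; freshly initialized when omitted.
#' @param cfg a [model_config()].
#' @return feature array `(H, W, D, base_channels)`.
#' @export
stem <- function(input, params = NULL, cfg = model_config()) {
  plain <- !is_ag(input)
  x <- as_ag(input)
  if (length(dim(x$value)) == 3L) x <- ag_reshape(x, c(dim(x$value), 1L))
  if (is.null(params)) params <- params_backbone(cfg)$stem
  y <- stem_forward(x, params, cfg)
  if (plain) y$value else y
}

backbone_shallow_forward <- function(x, p, cfg) {
  h <- stem_forward(x, p$stem, cfg)
  maps <- vector("list", cfg$shallow_stages)
  for (s in seq_len(cfg$shallow_stages)) {
    stride <- if (s == 1L) 1L else 2L
    h <- res_block_forward(h, p$stages[[s]], stride)
    maps[[s]] <- new_fmap(h, "shallow", s, 2L^(s - 1L))
  }
  maps
}

backbone_deep_forward <- function(x, p, cfg, min_extent = 4L) {
  h <- stem_forward(x, p$stem, cfg)
  maps <- vector("list", length(cfg$deep_grouping))
  stride_acc <- 1L
  for (g in seq_along(cfg$deep_grouping)) {
    for (b in seq_along(p$groups[[g]])) {
      want_stride <- if (b == 1L && g > 1L) 2L else 1L
      # stop downsampling once any extent would drop below min_extent
      if (want_stride == 2L && any(dim(h$value)[1:3] < min_extent))
        want_stride <- 1L
      if (want_stride == 2L) stride_acc <- stride_acc * 2L
      h <- res_block_forward(h, p$groups[[g]][[b]], want_stride)
    }
    maps[[g]] <- new_fmap(h, "deep", g, stride_acc)
  }
  maps
}

#' Shallow backbone forward pass
#'
#' Runs the high-resolution (2x-upsampled) image through the five-layer stem
#' and six residual stages, emitting one feature map per stage with strides
#' doubling from 1 to 32 relative to its input.
#'
#' @param image high-resolution single-channel image array.
#' @inheritParams stem
#' @return list of feature maps (each with `$x`, `$level`, `$scale`,
#'   `$stride`, `$channels`).
#' @export
shallow_forward <- function(image, params = NULL, cfg = model_config()) {
  x <- as_ag(image)
  if (length(dim(x$value)) == 3L) x <- ag_reshape(x, c(dim(x$value), 1L))
  if (is.null(params)) params <- params_backbone(cfg, deep = FALSE)
  backbone_shallow_forward(x, params, cfg)
}

#' Deep backbone forward pass
#'
#' Runs the low-resolution (2x-downsampled) image through the stem and nine
#' residual blocks grouped over six resolution scales (pattern 2-2-2-1-1-1),
#' so the deep pyramid aligns scale-for-scale with the shallow one.
#' Downsampling stops once a spatial extent would drop below 4 voxels; later
#' groups then refine at the coarsest reached scale.
#'
#' @param image low-resolution single-channel image array.
#' @inheritParams stem
#' @return list of feature maps, one per scale group.
#' @export
deep_forward <- function(image, params = NULL, cfg = model_config()) {
  x <- as_ag(image)
  if (length(dim(x$value)) == 3L) x <- ag_reshape(x, c(dim(x$value), 1L))
  if (is.null(params)) params <- params_backbone(cfg, deep = TRUE)
  backbone_deep_forward(x, params, cfg)
}

params_fpn <- function(cfg) {
  ch <- stage_channels(cfg)
  list(sh = lapply(seq_len(cfg$shallow_stages), function(s)
         params_conv(1L, ch[s], cfg$fpn_channels)),
       dp = lapply(seq_along(cfg$deep_grouping), function(g)
         params_conv(1L, ch[g], cfg$fpn_channels)))
}

#' Multi-scale feature pyramid fusion
#'
#' Fuses the two backbones' feature maps to a common channel width:
#' `F'[i,j] = Conv1x1(F[i,j]) + Up(F'[i,j-1]) + Up(F'[i+1,j])`, where `Up`
#' doubles the spatial resolution (trilinear), `i` indexes the backbone
#' (shallow above deep), `j` the scale, and terms whose index falls outside
#' the pyramid are omitted. Propagation runs from the deep backbone to the
#' shallow one and from coarse to fine, so semantic content flows down-level
#' and up-resolution.
#'
#' @param pyramid a list with elements `shallow` and `deep`, each a list of
#'   feature maps as returned by [shallow_forward()] / [deep_forward()];
#'   `deep` may be absent or empty.
#' @param params optional fusion parameters; freshly initialized when omitted.
#' @param cfg a [model_config()].
#' @return fused pyramid: list with `maps` (shallow-branch fused maps, finest
#'   first), `deep_maps`, and `fused = TRUE`.
#' @export
msfpn_fuse <- function(pyramid, params = NULL, cfg = model_config()) {
  sh <- pyramid$shallow
  dp <- pyramid$deep %||% list()
  if (length(sh) == 0L && length(dp) == 0L) stop("empty pyramid")
  if (is.null(params)) params <- params_fpn(cfg)
  gain <- cfg$fpn_upsample_gain

  proj <- function(m, pc) {
    y <- ag_conv3d(m$x, pc$w, pc$b, 1L)
    new_fmap(y, m$level, m$scale, m$stride)
  }
  up_to <- function(x, dims) {
    y <- ag_trilinear_resize(x, dims)
    if (gain != 1) y <- ag_scale(y, gain) else y
  }

  # deep branch: coarse -> fine, one fused map per distinct size; when the
  # downsampling ladder saturates and several groups share a size, their
  # projections are summed so every refinement group contributes
  fused_dp <- list()   # keyed by size string
  if (length(dp) > 0L) {
    keys <- vapply(dp, function(m) paste(fmap_size(m), collapse = "x"),
                   character(1))
    proj_by_key <- list()
    for (i in seq_along(dp)) {
      f <- proj(dp[[i]], params$dp[[dp[[i]]$scale]])
      if (is.null(proj_by_key[[keys[i]]])) proj_by_key[[keys[i]]] <- f
      else proj_by_key[[keys[i]]]$x <- ag_add(proj_by_key[[keys[i]]]$x, f$x)
    }
    uk <- unique(keys)
    sz <- vapply(uk, function(k) fmap_size(proj_by_key[[k]])[1], numeric(1))
    prev <- NULL
    for (k in uk[order(sz)]) {
      f <- proj_by_key[[k]]
      if (!is.null(prev))
        f$x <- ag_add(f$x, up_to(prev$x, fmap_size(f)))
      fused_dp[[k]] <- f
      prev <- f
    }
  }

  # shallow branch: coarse -> fine, with cross-backbone term from the deep
  # fused map at half the current size
  fused_sh <- vector("list", length(sh))
  if (length(sh) > 0L) {
    ord <- order(vapply(sh, function(m) fmap_size(m)[1], numeric(1)))
    prev <- NULL
    for (si in ord) {
      m <- sh[[si]]
      dims <- fmap_size(m)
      f <- proj(m, params$sh[[m$scale]])
      if (!is.null(prev))
        f$x <- ag_add(f$x, up_to(prev$x, dims))
      key <- paste(floor(dims / 2), collapse = "x")
      if (!is.null(fused_dp[[key]]))
        f$x <- ag_add(f$x, up_to(fused_dp[[key]]$x, dims))
      fused_sh[[si]] <- f
      prev <- f
    }
  }
  structure(list(maps = fused_sh, deep_maps = unname(fused_dp), fused = TRUE),
            class = "coretr_pyramid")
}
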