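# Decoder and full-network assembly: reshape the token sequence back to 3D
# grids, progressively upsample with transpose convolutions + residual
# refinement while merging pyramid skips, and emit voxel-wise logits.

#' Reshape a token matrix back to a 3D feature grid
#'
#' Exact inverse of the raster order used by [flatten_with_pos()] (H fastest,
#' then W, then D) for a single scale.
#'
#' @param seq a `token_sequence`, or an `N x C` token matrix.
#' @param dims target spatial dimensions `(H, W, D)`.
#' @param scale when `seq` covers several scales, which one to reshape.
#' @return feature array `(H, W, D, C)`.
#' @export
reshape_to_volume <- function(seq, dims, scale = 1L) {
  tok <- if (inherits(seq, "token_sequence")) {
    rows <- seq$scales[[scale]]$rows
    ag_rows(seq$tokens, rows)
  } else as_ag(seq)
  n <- nrow(tok$value)
  C <- ncol(tok$value)
  if (n != prod(dims))
    stop("sequence length ", n, " does not match prod(dims) = ", prod(dims))
  out <- ag_reshape(tok, c(dims, C))
  if (inherits(seq, "token_sequence") || is_ag(seq)) out else out$value
}

params_upsample_block <- function(cfg, cin, skip_ch, cout) {
  list(up = params_convT(2L, cin, cout),
       proj = params_conv(1L, cout + skip_ch, cout),
       block = params_res_block(cfg$res_kernel, cout, cout, 1L))
}

upsample_block_forward <- function(x, skip, p) {
  y <- ag_conv3d_T(x, p$up$w, p$up$b, 2L)
  if (!all(dim(y$value)[1:3] == dim(skip$value)[1:3]))
    stop("skip resolution must be exactly twice the input's")
  y <- ag_concat_channels(y, skip)
  y <- ag_conv3d(y, p$proj$w, p$proj$b, 1L)
  res_block_forward(y, p$block, 1L)
}

#' Decoder upsampling block
#'
#' Transpose convolution (kernel 2, stride 2) doubling the spatial
#' dimensions, concatenation with the encoder skip, a 1^3 projection, and one
#' residual refinement block.
#'
#' @param input feature array at the coarser resolution.
#' @param skip feature array at exactly twice the input's resolution.
#' @param out_channels output width (defaults to the input width).
#' @param params optional parameter set; freshly initialized when omitted.
#' @param cfg a [model_config()].
#' @export
upsample_block <- function(input, skip, out_channels = NULL, params = NULL,
                           cfg = model_config()) {
  plain <- !is_ag(input)
  x <- as_ag(input); s <- as_ag(skip)
  cin <- dim(x$value)[4]
  if (is.null(out_channels)) out_channels <- cin
  if (is.null(params))
    params <- params_upsample_block(cfg, cin, dim(s$value)[4], out_channels)
  y <- upsample_block_forward(x, s, params)
  if (plain) y$value else y
}

#' Segmentation head
#'
#' Final 1^3 convolution to a single channel of voxel-wise logits (no
#' activation; apply a sigmoid to obtain foreground probabilities).
#'
#' @param input full-resolution feature array.
#' @param params optional parameter set.
#' @export
segmentation_head <- function(input, params = NULL) {
  plain <- !is_ag(input)
  x <- as_ag(input)
  if (is.null(params)) params <- params_conv(1L, dim(x$value)[4], 1L)
  y <- ag_conv3d(x, params$w, params$b, 1L)
  if (plain) y$value else y
}

# Edge lengths of the shallow-branch stage outputs for this configuration
# (stride-2 stages, halving with a floor of 1 voxel).
shallow_sizes <- function(cfg) {
  sz <- if (cfg$multi_resolution_input) 2L * cfg$patch_size else
    cfg$patch_size
  out <- integer(cfg$shallow_stages)
  for (s in seq_len(cfg$shallow_stages)) {
    out[s] <- sz
    sz <- max(1L, as.integer(ceiling(sz / 2)))
  }
  out
}

n_decoder_stages <- function(cfg) {
  # one upsampling stage per distinct stage size below the native resolution
  length(unique(shallow_sizes(cfg)[shallow_sizes(cfg) < cfg$patch_size]))
}

params_decoder <- function(cfg) {
  nd <- n_decoder_stages(cfg)
  w <- decoder_widths(cfg, nd)
  stages <- vector("list", nd)
  cin <- cfg$fpn_channels
  for (j in seq_len(nd)) {
    stages[[j]] <- params_upsample_block(cfg, cin, cfg$fpn_channels, w[j])
    cin <- w[j]
  }
  list(stages = stages, head = params_conv(1L, w[nd], 1L))
}

#' Build a Co-ReTr model
#'
#' Initializes every parameter of the network described by a
#' [model_config()]: the two backbone CNNs, the pyramid fusion, the
#' deformable transformer, and the decoder. Initialization is He-normal for
#' convolution/linear weights, unit/zero for normalization affines, and zero
#' for the attention offset, weight, and output projections (so attention
#' starts as an identity-friendly uniform average at the reference
#' locations).
#'
#' @param config a [model_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return a `coretr_model`: list with `config` and the parameter tree
#'   `params`.
#' @export
coretr_model <- function(config = model_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  params <- list(shallow = params_backbone(config, deep = FALSE),
                 deep = params_backbone(config, deep = TRUE),
                 fpn = params_fpn(config),
                 transformer = params_transformer(config),
                 decoder = params_decoder(config))
  structure(list(config = config, params = params), class = "coretr_model")
}

#' @export
print.coretr_model <- function(x, ...) {
  fl <- params_flatten(x$params, "p")
  n <- sum(vapply(fl, function(t) length(t$value), numeric(1)))
  cat("<coretr_model> ", length(fl), " parameter arrays, ",
      format(n, big.mark = ","), " parameters\n", sep = "")
  cat("  base_channels=", x$config$base_channels,
      " fpn_channels=", x$config$fpn_channels,
      " transformer_layers=", x$config$n_layers,
      if (!x$config$use_transformer) " (transformer bypassed)" else "",
      if (!x$config$multi_resolution_input) " (single-resolution input)" else "",
      "\n", sep = "")
  invisible(x)
}

# Internal forward pass on an autograd tensor (H, W, D, 1). Returns logits
# tensor (H, W, D, 1).
coretr_forward_ag <- function(model, x) {
  cfg <- model$config
  p <- model$params
  dims <- dim(x$value)[1:3]
  if (any(dims %% 16L != 0L))
    stop("patch dimensions must be divisible by 16, got ",
         paste(dims, collapse = "x"))

  if (cfg$multi_resolution_input) {
    hi <- ag_trilinear_resize(x, dims * 2L)
    lo <- ag_avgpool2(x)
  } else {
    hi <- x
    lo <- x
  }
  sh <- backbone_shallow_forward(hi, p$shallow, cfg)
  dp <- backbone_deep_forward(lo, p$deep, cfg)
  pyr <- msfpn_fuse(list(shallow = sh, deep = dp), p$fpn, cfg)

  # maps coarser than native resolution, coarsest first, plus the native
  # map; when the halving ladder saturates, several stages share a size --
  # the most-processed (last) map of each size feeds the decoder
  sizes <- vapply(pyr$maps, function(m) fmap_size(m)[1], numeric(1))
  native <- dims[1]
  last_per_size <- vapply(unique(sizes), function(s) max(which(sizes == s)),
                          integer(1))
  cand <- last_per_size[sizes[last_per_size] < native]
  coarse_idx <- cand[order(sizes[cand])]
  native_idx <- max(which(sizes == native))

  if (cfg$use_transformer) {
    nt <- min(cfg$token_scales, length(coarse_idx))
    tok_idx <- coarse_idx[seq_len(nt)]
    tseq <- flatten_with_pos(pyr$maps[tok_idx])
    tseq <- transformer_forward(tseq, cfg, p$transformer)
    for (i in seq_along(tok_idx)) {
      m <- pyr$maps[[tok_idx[i]]]
      m$x <- reshape_to_volume(tseq, fmap_size(m), scale = i)
      pyr$maps[[tok_idx[i]]] <- m
    }
  }

  h <- pyr$maps[[coarse_idx[1]]]$x
  for (j in seq_along(coarse_idx)) {
    nxt <- if (j < length(coarse_idx)) coarse_idx[j + 1] else native_idx
    skip <- pyr$maps[[nxt]]$x
    if (j == length(coarse_idx) && cfg$multi_resolution_input) {
      # fold the 2x-resolution map into the native skip
      hi_idx <- which(sizes == 2L * native)[1]
      if (!is.na(hi_idx))
        skip <- ag_add(skip, ag_avgpool2(pyr$maps[[hi_idx]]$x))
    }
    h <- upsample_block_forward(h, skip, p$decoder$stages[[j]])
  }
  ag_conv3d(h, p$decoder$head$w, p$decoder$head$b, 1L)
}

#' Full network forward pass
#'
#' Runs a normalized patch through the complete pipeline: multi-resolution
#' branch preparation, the two backbones, pyramid fusion, the (optional)
#' deformable transformer, and the decoder, producing voxel-wise logits at
#' the patch's native resolution.
#'
#' @param model a [coretr_model()] (or a checkpoint's model).
#' @param patch numeric 3D array in `[0, 1]`, each dimension divisible by 16.
#' @return 3D array of logits with the same dimensions as `patch`.
#' @export
coretr_forward <- function(model, patch) {
  stopifnot(inherits(model, "coretr_model"))
  x <- ag_tensor(array(as.numeric(patch), c(dim(patch)[1:3], 1L)))
  y <- ag_no_grad(coretr_forward_ag(model, x))
  array(y$value, dim(patch)[1:3])
}
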