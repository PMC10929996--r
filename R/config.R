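#' Model configuration
#'
#' Collects every architectural hyperparameter of the network: channel widths
#' of the convolutional backbones, depth of the deformable transformer,
#' attention geometry, and the two ablation switches (multi-resolution input
#' and the transformer module).
#'
#' The encoder runs two backbones: a *shallow* branch on the 2x-upsampled
#' patch (six residual stages) and a *deep* branch on the 2x-downsampled
#' patch (nine residual blocks grouped over six resolution scales,
#' `deep_grouping`). Channel width doubles per downsampling stage from
#' `base_channels`, capped at `max_channels`. The fused feature pyramid and
#' the transformer tokens share a common width `fpn_channels`.
#'
#' @param patch_size cubic patch edge length in voxels; must be divisible
#'   by 16 so every backbone stage has integral extent.
#' @param base_channels width of the first backbone stage.
#' @param max_channels cap on per-stage width.
#' @param fpn_channels common channel count of the fused pyramid and of the
#'   transformer tokens; must be divisible by `n_heads`. The default
#'   `3 * base_channels` keeps the per-axis positional-encoding budget
#'   (`fpn_channels / 3`) even.
#' @param res_kernel kernel of the residual-block convolution (5 by default).
#' @param stem_kernels kernels of the five stem Conv-IN-ReLU layers.
#' @param shallow_stages,deep_blocks,deep_grouping backbone depth layout.
#' @param n_layers,n_heads,n_points transformer depth, attention heads, and
#'   sampling points per head per scale.
#' @param ffn_mult feed-forward width as a multiple of `fpn_channels`.
#' @param token_scales how many of the coarsest pyramid scales become tokens.
#' @param multi_resolution_input if `FALSE`, both backbones see the
#'   native-resolution patch (ablation arm).
#' @param use_transformer if `FALSE`, the fused pyramid bypasses the
#'   transformer entirely (ablation arm).
#' @param fpn_upsample_gain scalar applied to upsampled pyramid terms; 1 reads
#'   "2x Upsample" as spatial doubling only, 2 additionally doubles values.
#' @return a `coretr_config` list.
#' @export
model_config <- function(patch_size = 96L,
                         base_channels = 32L,
                         max_channels = 320L,
                         fpn_channels = 3L * base_channels,
                         res_kernel = 5L,
                         stem_kernels = c(3L, 1L, 3L, 1L, 3L),
                         shallow_stages = 6L,
                         deep_blocks = 9L,
                         deep_grouping = c(2L, 2L, 2L, 1L, 1L, 1L),
                         n_layers = 4L,
                         n_heads = 6L,
                         n_points = 4L,
                         ffn_mult = 4L,
                         token_scales = 3L,
                         multi_resolution_input = TRUE,
                         use_transformer = TRUE,
                         fpn_upsample_gain = 1) {
  if (patch_size %% 16L != 0L)
    stop("patch_size must be divisible by 16")
  if (fpn_channels %% n_heads != 0L)
    stop("fpn_channels must be divisible by n_heads")
  if (sum(deep_grouping) != deep_blocks)
    stop("deep_grouping must sum to deep_blocks")
  if (length(deep_grouping) != shallow_stages)
    stop("deep_grouping must have one entry per shallow stage")
  cfg <- list(patch_size = as.integer(patch_size),
              in_channels = 1L,
              base_channels = as.integer(base_channels),
              max_channels = as.integer(max_channels),
              fpn_channels = as.integer(fpn_channels),
              res_kernel = as.integer(res_kernel),
              stem_kernels = as.integer(stem_kernels),
              shallow_stages = as.integer(shallow_stages),
              deep_blocks = as.integer(deep_blocks),
              deep_grouping = as.integer(deep_grouping),
              n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads),
              n_points = as.integer(n_points),
              ffn_mult = as.integer(ffn_mult),
              token_scales = as.integer(token_scales),
              multi_resolution_input = isTRUE(multi_resolution_input),
              use_transformer = isTRUE(use_transformer),
              fpn_upsample_gain = fpn_upsample_gain)
  class(cfg) <- "coretr_config"
  cfg
}

# per-stage channel widths
stage_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$shallow_stages) - 1L),
       cfg$max_channels)
}

# decoder stage widths, coarse to fine
decoder_widths <- function(cfg, n_stages) {
  pmax(cfg$base_channels, cfg$fpn_channels %/% 2L^(seq_len(n_stages) - 1L))
}
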