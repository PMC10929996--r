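# Deformable transformer: 3D sinusoidal positional encoding, pyramid
# flattening to a token sequence, deformable self-attention over a small set
# of continuous sampling locations, and the stacked DeTrans layers.

#' Sinusoidal positional encoding table for one axis
#'
#' For axis position `pos` (0-based) and channel-pair index `k`, the table
#' holds `sin(pos * v)` and `cos(pos * v)` in adjacent columns, with
#' `v = 1 / 10000^(2k / (channels/3))`. Each of the three axes receives a
#' third of the channel budget, so `channels` must be divisible by 6 (three
#' axes times sin/cos pairs); the per-axis table has `channels/3` columns.
#'
#' @param length number of positions along the axis.
#' @param channels total token channel count `C` (divisible by 6).
#' @return `length x channels/3` matrix with values in `[-1, 1]`.
#' @export
positional_encoding <- function(length, channels) {
  if (channels %% 6L != 0L)
    stop("channels must be divisible by 6 (three axes x sin/cos pairs)")
  cpa <- channels %/% 3L                    # per-axis width, even
  ks <- seq_len(cpa %/% 2L) - 1L
  v <- 1 / 10000^(2 * ks / cpa)
  pos <- seq_len(length) - 1L
  ang <- outer(pos, v)                      # length x (cpa/2)
  tab <- matrix(0, length, cpa)
  tab[, 2L * ks + 1L] <- sin(ang)
  tab[, 2L * ks + 2L] <- cos(ang)
  tab
}

# Positional vector block for a grid: rows in raster order (h fastest),
# columns = C (concatenated per-axis tables, zero-padded if C %% 6 != 0).
grid_pos_encoding <- function(dims, channels) {
  c6 <- 6L * (channels %/% 6L)
  cpa <- c6 %/% 3L
  n <- prod(dims)
  enc <- matrix(0, n, channels)
  if (c6 > 0L) {
    th <- positional_encoding(dims[1], c6)
    tw <- positional_encoding(dims[2], c6)
    td <- positional_encoding(dims[3], c6)
    idx <- arrayInd(seq_len(n), dims)
    enc[, seq_len(cpa)] <- th[idx[, 1], , drop = FALSE]
    enc[, cpa + seq_len(cpa)] <- tw[idx[, 2], , drop = FALSE]
    enc[, 2L * cpa + seq_len(cpa)] <- td[idx[, 3], , drop = FALSE]
  }
  enc
}

#' Flatten a fused pyramid into a token sequence
#'
#' Tokens are the feature vectors of the selected pyramid scales in a fixed
#' raster order (scale-major, then H fastest, then W, then D). Each token
#' carries a 3D positional-encoding vector (concatenation of the three
#' per-axis tables at the token's grid position) and its normalized grid
#' coordinate; the encoding is combined with the token by element-wise
#' addition at the transformer input.
#'
#' @param pyramid a fused pyramid from [msfpn_fuse()], or a list of feature
#'   maps.
#' @param scales indices (into the coarsest-first ordering) of the scales to
#'   tokenize; `NULL` selects all supplied maps.
#' @return a `token_sequence`: list with `tokens` (N x C), `encodings`
#'   (N x C), and per-scale metadata (`dims`, `rows`, `ref` normalized
#'   coordinates).
#' @export
flatten_with_pos <- function(pyramid, scales = NULL) {
  maps <- if (!is.null(pyramid$maps)) {
    if (!isTRUE(pyramid$fused)) stop("pyramid must be fused")
    pyramid$maps
  } else pyramid
  # order coarsest first for tokenization
  sizes <- vapply(maps, function(m) prod(dim(m$x$value)[1:3]), numeric(1))
  ord <- order(sizes)
  maps <- maps[ord]
  if (!is.null(scales)) maps <- maps[scales]
  if (length(maps) == 0L) stop("no maps selected")
  C <- dim(maps[[1]]$x$value)[4]

  tok_list <- list(); meta <- list(); enc_list <- list()
  row0 <- 0L
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    dims <- dim(m$x$value)[1:3]
    n <- prod(dims)
    tok_list[[i]] <- ag_reshape(m$x, c(n, C))
    enc_list[[i]] <- grid_pos_encoding(dims, C)
    idx <- arrayInd(seq_len(n), dims) - 1L
    ref <- sweep(idx, 2L, pmax(dims - 1L, 1L), "/")
    ref[, dims == 1L] <- 0.5
    meta[[i]] <- list(dims = dims, rows = row0 + seq_len(n), ref = ref)
    row0 <- row0 + n
  }
  structure(list(tokens = ag_rbind(tok_list),
                 encodings = do.call(rbind, enc_list),
                 scales = meta, channels = C),
            class = "token_sequence")
}

params_detrans_layer <- function(C, n_heads, n_scales, n_points, ffn_dim) {
  hsp <- n_heads * n_scales * n_points
  list(ln1 = params_norm(C),
       v = params_linear(C, C),
       off = params_linear(C, hsp * 3L, zero = TRUE),
       attn = params_linear(C, hsp, zero = TRUE),
       o = params_linear(C, C, zero = TRUE),
       ln2 = params_norm(C),
       ffn1 = params_linear(C, ffn_dim),
       ffn2 = params_linear(ffn_dim, C))
}

params_transformer <- function(cfg) {
  C <- cfg$fpn_channels
  lapply(seq_len(cfg$n_layers), function(l)
    params_detrans_layer(C, cfg$n_heads, cfg$token_scales, cfg$n_points,
                         cfg$ffn_mult * C))
}

# Core deformable self-attention on a token matrix. Every query predicts, per
# head, `n_points` continuous offsets around its reference location in every
# tokenized scale, plus attention weights softmax-normalized over
# (scales x points); the output is the weighted sum of value features sampled
# trilinearly at those locations. Cost is linear in N x heads x scales x
# points -- never quadratic in N.
deformable_attention_core <- function(x, seq_meta, p, n_heads, n_points,
                                      return_details = FALSE) {
  C <- ncol(x$value)
  n_scales <- length(seq_meta)
  dh <- C %/% n_heads
  N <- nrow(x$value)

  V <- ag_linear(x, p$v$w, p$v$b)
  off <- ag_linear(x, p$off$w, p$off$b)       # N x (h*s*p*3)
  aw <- ag_linear(x, p$attn$w, p$attn$b)      # N x (h*s*p)

  # reference location of every query, expressed in each scale's grid
  refs <- do.call(rbind, lapply(seq_meta, function(mi) mi$ref))  # N x 3, [0,1]

  head_outs <- vector("list", n_heads)
  details <- if (return_details)
    list(offsets = off$value, weights = vector("list", n_heads)) else NULL
  sp <- n_scales * n_points
  for (h in seq_len(n_heads)) {
    w_h <- ag_softmax_rows(ag_cols(aw, (h - 1L) * sp + seq_len(sp)))
    if (return_details) details$weights[[h]] <- w_h$value
    acc <- NULL
    for (s in seq_len(n_scales)) {
      dims <- seq_meta[[s]]$dims
      Vg <- ag_reshape(ag_rows(ag_cols(V, (h - 1L) * dh + seq_len(dh)),
                               seq_meta[[s]]$rows),
                       c(dims, dh))
      ref_s <- sweep(refs, 2L, pmax(dims - 1L, 1L), "*")  # voxel units
      for (pt in seq_len(n_points)) {
        col0 <- ((h - 1L) * n_scales * n_points + (s - 1L) * n_points +
                 (pt - 1L)) * 3L
        o3 <- ag_cols(off, col0 + 1:3)
        coords <- ag_add(o3, ref_s)
        sampled <- ag_grid_sample(Vg, coords)              # N x dh
        wcol <- ag_cols(w_h, (s - 1L) * n_points + pt)
        term <- ag_colmul(sampled, wcol)
        acc <- if (is.null(acc)) term else ag_add(acc, term)
      }
    }
    head_outs[[h]] <- acc
  }
  out <- ag_cbind(head_outs)
  out <- ag_linear(out, p$o$w, p$o$b)
  if (return_details) attr(out, "details") <- details
  out
}

#' Deformable self-attention over a token sequence
#'
#' @param seq a `token_sequence` from [flatten_with_pos()].
#' @param cfg a [model_config()] supplying `n_heads` and `n_points`.
#' @param weights optional layer parameter set; freshly initialized when
#'   omitted (offset and weight heads start at zero, so sampling begins at
#'   the reference locations with uniform weights).
#' @param return_details if `TRUE`, attach predicted offsets and attention
#'   weights (per head) as the `"details"` attribute.
#' @return the sequence with transformed tokens (same length and width).
#' @export
deformable_attention <- function(seq, cfg = model_config(), weights = NULL,
                                 return_details = FALSE) {
  if (nrow(seq$tokens$value) == 0L) stop("empty token sequence")
  C <- seq$channels
  if (is.null(weights))
    weights <- params_detrans_layer(C, cfg$n_heads, length(seq$scales),
                                    cfg$n_points, cfg$ffn_mult * C)
  out <- deformable_attention_core(seq$tokens, seq$scales, weights,
                                   cfg$n_heads, cfg$n_points, return_details)
  seq$tokens <- out
  seq
}

detrans_layer_forward <- function(x, seq_meta, p, n_heads, n_points) {
  a <- ag_layer_norm(x, p$ln1$g, p$ln1$b)
  a <- deformable_attention_core(a, seq_meta, p, n_heads, n_points)
  x <- ag_add(x, a)
  f <- ag_layer_norm(x, p$ln2$g, p$ln2$b)
  f <- ag_linear(f, p$ffn1$w, p$ffn1$b)
  f <- ag_relu(f)
  f <- ag_linear(f, p$ffn2$w, p$ffn2$b)
  ag_add(x, f)
}

#' One DeTrans layer
#'
#' Pre-norm transformer layer built on deformable self-attention:
#' `x + Attn(LN(x))` followed by `x + FFN(LN(x))`. With the attention output
#' projection and the second feed-forward weight at zero, the layer is
#' exactly the identity map -- the skip connections carry the input through
#' untouched.
#'
#' @inheritParams deformable_attention
#' @export
detrans_layer <- function(seq, cfg = model_config(), weights = NULL) {
  C <- seq$channels
  if (is.null(weights))
    weights <- params_detrans_layer(C, cfg$n_heads, length(seq$scales),
                                    cfg$n_points, cfg$ffn_mult * C)
  seq$tokens <- detrans_layer_forward(seq$tokens, seq$scales, weights,
                                      cfg$n_heads, cfg$n_points)
  seq
}

#' Stacked deformable transformer
#'
#' Adds the 3D positional encodings to the tokens (element-wise, input only)
#' and applies `cfg$n_layers` DeTrans layers in sequence.
#'
#' @inheritParams deformable_attention
#' @param weights list of per-layer parameter sets; freshly initialized when
#'   omitted.
#' @param add_encodings add the positional encodings before the first layer.
#' @export
transformer_forward <- function(seq, cfg = model_config(), weights = NULL,
                                add_encodings = TRUE) {
  stopifnot(cfg$n_layers >= 1L)
  C <- seq$channels
  if (is.null(weights))
    weights <- lapply(seq_len(cfg$n_layers), function(l)
      params_detrans_layer(C, cfg$n_heads, length(seq$scales), cfg$n_points,
                           cfg$ffn_mult * C))
  x <- seq$tokens
  if (add_encodings) x <- ag_add(x, ag_tensor(seq$encodings))
  for (l in seq_along(weights))
    x <- detrans_layer_forward(x, seq$scales, weights[[l]],
                               cfg$n_heads, cfg$n_points)
  seq$tokens <- x
  seq
}
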