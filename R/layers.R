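# Parameter containers and the elementary network blocks.
#
# A "param set" is a named list of ag_tensor parameters (requires_grad = TRUE).
# Constructors draw from the current R RNG so model initialization is
# reproducible under set.seed().

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_param <- function(value) ag_tensor(value, requires_grad = TRUE)

params_conv <- function(k, cin, cout, zero = FALSE) {
  w <- if (zero) array(0, c(k, k, k, cin, cout))
       else he_init(c(k, k, k, cin, cout), k^3 * cin)
  list(w = new_param(w), b = new_param(numeric(cout)))
}

params_norm <- function(c) {
  list(g = new_param(rep(1, c)), b = new_param(numeric(c)))
}

params_linear <- function(cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, cin, cout)
       else matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  list(w = new_param(w), b = new_param(numeric(cout)))
}

params_convT <- function(s, cin, cout) {
  list(w = new_param(he_init(c(s, s, s, cin, cout), cin)),
       b = new_param(numeric(cout)))
}

#' Convolution--instance-normalization--ReLU block
#'
#' The elementary unit of both backbones: a 3D convolution with "same"
#' padding, per-channel instance normalization, then ReLU. Stride 2 halves
#' each spatial dimension.
#'
#' @param input a feature array `(H, W, D, C)` (a plain array or an internal
#'   autograd tensor).
#' @param out_channels number of output channels.
#' @param kernel odd kernel edge length.
#' @param stride 1 or 2.
#' @param params optional parameter set from a model; freshly initialized
#'   from the current RNG when omitted.
#' @return feature array of the same kind as the input.
#' @export
conv_in_relu <- function(input, out_channels, kernel = 3L, stride = 1L,
                         params = NULL) {
  plain <- !is_ag(input)
  x <- as_ag(input)
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (any(kernel > dim(x$value)[1:3])) stop("kernel larger than input extent")
  cin <- dim(x$value)[4]
  if (is.null(params)) {
    params <- list(conv = params_conv(kernel, cin, out_channels),
                   norm = params_norm(out_channels))
  }
  y <- ag_conv3d(x, params$conv$w, params$conv$b, stride)
  y <- ag_instance_norm(y, params$norm$g, params$norm$b)
  y <- ag_relu(y)
  if (plain) y$value else y
}

cir_forward <- function(x, p, stride = 1L) {
  y <- ag_conv3d(x, p$conv$w, p$conv$b, stride)
  ag_instance_norm_relu(y, p$norm$g, p$norm$b)
}

params_cir <- function(k, cin, cout) {
  list(conv = params_conv(k, cin, cout), norm = params_norm(cout))
}

# Residual block: transform = Conv(k^3) -> IN -> ReLU -> Conv(1^3) -> IN,
# added to an identity shortcut (1^3 strided projection when the channel
# count or resolution changes). No post-activation, so zeroing the transform
# weights leaves the shortcut exactly.
params_res_block <- function(k, cin, cout, stride = 1L) {
  p <- list(conv5 = params_conv(k, cin, cout),
            n1 = params_norm(cout),
            conv1 = params_conv(1L, cout, cout),
            n2 = params_norm(cout))
  if (cin != cout || stride != 1L) p$proj <- params_conv(1L, cin, cout)
  p
}

res_block_forward <- function(x, p, stride = 1L) {
  t <- ag_conv3d(x, p$conv5$w, p$conv5$b, stride)
  t <- ag_instance_norm_relu(t, p$n1$g, p$n1$b)
  t <- ag_conv3d(t, p$conv1$w, p$conv1$b, 1L)
  t <- ag_instance_norm(t, p$n2$g, p$n2$b)
  s <- if (!is.null(p$proj)) ag_conv3d(x, p$proj$w, p$proj$b, stride) else x
  ag_add(t, s)
}

#' Residual block
#'
#' One backbone stage unit: a `res_kernel`^3 Conv-IN-ReLU transform refined by
#' a 1^3 convolution, plus an identity shortcut (1^3 projection when the
#' channel count changes or the stage downsamples).
#'
#' @param input feature array `(H, W, D, C)`.
#' @param out_channels output width; defaults to the input width.
#' @param kernel transform kernel (default 5).
#' @param stride 1, or 2 for a downsampling stage.
#' @param params optional parameter set; freshly initialized when omitted.
#' @export
residual_block <- function(input, out_channels = NULL, kernel = 5L,
                           stride = 1L, params = NULL) {
  plain <- !is_ag(input)
  x <- as_ag(input)
  cin <- dim(x$value)[4]
  if (is.null(out_channels)) out_channels <- cin
  if (is.null(params))
    params <- params_res_block(kernel, cin, out_channels, stride)
  y <- res_block_forward(x, params, stride)
  if (plain) y$value else y
}

# Deep copies / flat views of a parameter set (nested named lists of
# ag_tensor leaves).
params_walk <- function(p, f) {
  if (is_ag(p)) return(f(p))
  if (is.list(p)) return(lapply(p, params_walk, f = f))
  p
}

params_flatten <- function(p, prefix = "") {
  out <- list()
  rec <- function(node, name) {
    if (is_ag(node)) {
      out[[name]] <<- node
    } else if (is.list(node)) {
      nms <- names(node) %||% as.character(seq_along(node))
      nms[nms == ""] <- as.character(which(nms == ""))
      for (i in seq_along(node)) rec(node[[i]], paste0(name, ".", nms[i]))
    }
  }
  rec(p, prefix)
  out
}

params_values <- function(p) params_walk(p, function(t) t$value)

params_load_values <- function(p, v) {
  stopifnot(is.list(p), length(p) == length(v))
  for (i in seq_along(p)) {
    if (is_ag(p[[i]])) p[[i]]$value <- v[[i]]
    else if (is.list(p[[i]])) params_load_values(p[[i]], v[[i]])
  }
  invisible(p)
}
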