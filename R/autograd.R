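#' @useDynLib coretr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal tape-based reverse-mode automatic differentiation over R arrays.
#
# A tensor is an environment holding `value` (numeric array/matrix), `grad`
# (accumulated cotangent, same shape) and `requires_grad`. During a recorded
# forward pass every differentiable op appends a record to the tape:
# (output tensor, input tensors, backward closure). `ag_backward()` walks the
# tape in reverse, calling each closure with the output cotangent and
# accumulating into the inputs. Batch size is always 1, so there is no batch
# axis anywhere.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL      # list of records while recording, else NULL
.ag$n <- 0L

ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

# Wrap plain arrays as constant tensors so ops can mix the two freely.
as_ag <- function(x) if (is_ag(x)) x else ag_tensor(x)

ag_recording <- function() !is.null(.ag$tape)

ag_record <- function(out, inputs, backward) {
  if (ag_recording() && out$requires_grad) {
    .ag$n <- .ag$n + 1L
    .ag$tape[[.ag$n]] <- list(out = out, inputs = inputs, backward = backward)
  }
  out
}

# Run `expr` with a fresh tape; returns the expression's value. The tape stays
# live until ag_backward()/ag_clear_tape() so the caller can backpropagate.
ag_with_tape <- function(expr) {
  .ag$tape <- vector("list", 512L)
  .ag$n <- 0L
  expr
}

ag_clear_tape <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

# Evaluate without recording (inference mode).
ag_no_grad <- function(expr) {
  old_tape <- .ag$tape; old_n <- .ag$n
  .ag$tape <- NULL; .ag$n <- 0L
  on.exit({ .ag$tape <- old_tape; .ag$n <- old_n })
  expr
}

ag_accum <- function(t, g) {
  if (!t$requires_grad) return(invisible(NULL))
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar tensor through the recorded tape.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  if (!ag_recording()) stop("no tape: call inside ag_with_tape()")
  loss$grad <- 1
  if (.ag$n > 0L) {
    for (i in seq(.ag$n, 1L)) {
      rec <- .ag$tape[[i]]
      g <- rec$out$grad
      if (is.null(g)) next
      gs <- rec$backward(g)
      ins <- rec$inputs
      for (j in seq_along(ins)) {
        gj <- gs[[j]]
        if (is.null(gj)) next
        t <- ins[[j]]
        if (!t$requires_grad) next
        if (is.null(t$grad)) t$grad <- gj else t$grad <- t$grad + gj
      }
      rec$out$grad <- NULL   # free cotangents early (params are inputs)
    }
  }
  ag_clear_tape()
  invisible(NULL)
}

ag_any_grad <- function(...) {
  inputs <- list(...)
  any(vapply(inputs, function(i) i$requires_grad, logical(1)))
}

# ---- primitive ops -------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  out <- ag_tensor(a$value + b$value, ag_any_grad(a, b))
  ag_record(out, list(a, b), function(g) list(g, g))
}

ag_scale <- function(a, s) {
  out <- ag_tensor(a$value * s, a$requires_grad)
  ag_record(out, list(a), function(g) list(g * s))
}

ag_relu <- function(a) {
  y <- .cpp_relu_forward(a$value)
  out <- ag_tensor(y, a$requires_grad)
  ag_record(out, list(a), function(g) list(.cpp_relu_backward(g, y)))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  out <- ag_tensor(s, a$requires_grad)
  ag_record(out, list(a), function(g) list(g * s * (1 - s)))
}

ag_reshape <- function(a, dims) {
  old <- dim(a$value) %||% length(a$value)
  v <- a$value
  dim(v) <- dims
  out <- ag_tensor(v, a$requires_grad)
  ag_record(out, list(a), function(g) { dim(g) <- old; list(g) })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# x: N x Cin matrix, w: Cin x Cout, b: length Cout or NULL
ag_linear <- function(x, w, b = NULL) {
  y <- x$value %*% w$value
  if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
  out <- ag_tensor(y, ag_any_grad(x, w) || (!is.null(b) && b$requires_grad))
  ins <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value; wv <- w$value
  ag_record(out, ins, function(g) {
    gx <- g %*% t(wv)
    gw <- t(xv) %*% g
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(g))
  })
}

# Row-wise softmax of an N x M matrix.
ag_softmax_rows <- function(x) {
  v <- x$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  out <- ag_tensor(s, x$requires_grad)
  ag_record(out, list(x), function(g) {
    dot <- rowSums(g * s)
    list((g - dot) * s)
  })
}

# Instance normalization on an (H, W, D, C) tensor: per-channel spatial
# standardization, then affine (gamma, beta of length C).
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  f <- .cpp_instance_norm_forward(x$value, d, gamma$value, beta$value, eps,
                                  FALSE)
  out <- ag_tensor(f$y, ag_any_grad(x, gamma, beta))
  ag_record(out, list(x, gamma, beta), function(g) {
    b <- .cpp_instance_norm_backward(g, d, f$xhat, f$inv, gamma$value)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# Fused instance norm + ReLU (one pass, one tape node).
ag_instance_norm_relu <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  f <- .cpp_instance_norm_forward(x$value, d, gamma$value, beta$value, eps,
                                  TRUE)
  out <- ag_tensor(f$y, ag_any_grad(x, gamma, beta))
  ag_record(out, list(x, gamma, beta), function(g) {
    b <- .cpp_instance_norm_backward(g, d, f$xhat, f$inv, gamma$value, f$y)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# Layer normalization over the channel (second) axis of an N x C matrix.
ag_layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc * xc)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  out <- ag_tensor(y, ag_any_grad(x, gamma, beta))
  ag_record(out, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gamma$value, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

# 3D convolution, "same" padding, stride 1 or 2. x: (H,W,D,Cin),
# w: (k,k,k,Cin,Cout), b: length Cout.
ag_conv3d <- function(x, w, b, stride = 1L) {
  dw <- dim(w$value)
  k <- dw[1]; cin <- dw[4]; cout <- dw[5]
  if (dim(x$value)[4] != cin)
    stop("conv input has ", dim(x$value)[4], " channels, weights expect ", cin)
  pad <- (k - 1L) %/% 2L
  xd <- dim(x$value)[1:3]
  y <- .cpp_conv3d_forward(x$value, xd, w$value, b$value, k, cin, cout,
                           as.integer(stride), pad)
  out <- ag_tensor(y, ag_any_grad(x, w, b))
  xv <- x$value
  ag_record(out, list(x, w, b), function(g) {
    gr <- .cpp_conv3d_backward(xv, xd, w$value, g, k, cin, cout,
                               as.integer(stride), pad)
    list(gr$dx, gr$dw, gr$db)
  })
}

# Transpose convolution with kernel == stride (checkerboard-free upsampling).
ag_conv3d_T <- function(x, w, b, stride = 2L) {
  dw <- dim(w$value)
  s <- dw[1]; cin <- dw[4]; cout <- dw[5]
  xd <- dim(x$value)[1:3]
  y <- .cpp_convT3d_forward(x$value, xd, w$value, b$value, s, cin, cout)
  out <- ag_tensor(y, ag_any_grad(x, w, b))
  xv <- x$value
  ag_record(out, list(x, w, b), function(g) {
    gr <- .cpp_convT3d_backward(xv, xd, w$value, g, s, cin, cout)
    list(gr$dx, gr$dw, gr$db)
  })
}

ag_trilinear_resize <- function(x, out_dims) {
  xd <- dim(x$value)
  od <- as.integer(out_dims)
  y <- .cpp_trilinear_resize(x$value, xd, od)
  out <- ag_tensor(y, x$requires_grad)
  ag_record(out, list(x), function(g)
    list(.cpp_trilinear_resize_backward(g, xd, od)))
}

ag_avgpool2 <- function(x) {
  xd <- dim(x$value)
  stopifnot(all(xd[1:3] %% 2L == 0L))
  y <- .cpp_avgpool2_forward(x$value, xd)
  out <- ag_tensor(y, x$requires_grad)
  ag_record(out, list(x), function(g) list(.cpp_avgpool2_backward(g, xd)))
}

# Trilinear sampling of grid (H,W,D,C) at continuous voxel coords (N x 3,
# 0-based); differentiable in both the grid and the coordinates.
ag_grid_sample <- function(grid, coords) {
  gd <- dim(grid$value)
  y <- .cpp_grid_sample(grid$value, gd, coords$value)
  out <- ag_tensor(y, ag_any_grad(grid, coords))
  gv <- grid$value; cv <- coords$value
  ag_record(out, list(grid, coords), function(g) {
    gr <- .cpp_grid_sample_backward(gv, gd, cv, g)
    list(gr$dx, gr$dcoords)
  })
}

# Concatenate along the channel (last) axis of (H,W,D,C) tensors.
ag_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  y <- array(c(a$value, b$value), c(da[1:3], da[4] + db[4]))
  out <- ag_tensor(y, ag_any_grad(a, b))
  na <- prod(da)
  ag_record(out, list(a, b), function(g) {
    list(array(g[seq_len(na)], da), array(g[-seq_len(na)], db))
  })
}

# Column slice of an N x M matrix.
ag_cols <- function(x, idx) {
  y <- x$value[, idx, drop = FALSE]
  out <- ag_tensor(y, x$requires_grad)
  nc <- ncol(x$value); nr <- nrow(x$value)
  ag_record(out, list(x), function(g) {
    full <- matrix(0, nr, nc)
    full[, idx] <- g
    list(full)
  })
}

# Row slice of an N x M matrix.
ag_rows <- function(x, idx) {
  y <- x$value[idx, , drop = FALSE]
  out <- ag_tensor(y, x$requires_grad)
  nc <- ncol(x$value); nr <- nrow(x$value)
  ag_record(out, list(x), function(g) {
    full <- matrix(0, nr, nc)
    full[idx, ] <- g
    list(full)
  })
}

# Stack a list of N_i x C matrices by rows.
ag_rbind <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  y <- do.call(rbind, vals)
  out <- ag_tensor(y, any(vapply(xs, function(x) x$requires_grad, logical(1))))
  ns <- vapply(vals, nrow, integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  ag_record(out, xs, function(g)
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}

# Multiply every column of an N x M matrix by a length-N weight vector
# (N x 1 matrix), as used for attention weighting.
ag_colmul <- function(mat, vec) {
  v <- as.numeric(vec$value)
  out <- ag_tensor(mat$value * v, ag_any_grad(mat, vec))
  mv <- mat$value
  ag_record(out, list(mat, vec), function(g) {
    list(g * v, matrix(rowSums(g * mv), ncol = 1L))
  })
}

# Column-bind a list of N x M_i matrices.
ag_cbind <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  y <- do.call(cbind, vals)
  out <- ag_tensor(y, any(vapply(xs, function(x) x$requires_grad, logical(1))))
  ncs <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  ag_record(out, xs, function(g)
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

# Elementwise product (used for attention weighting).
ag_mul <- function(a, b) {
  out <- ag_tensor(a$value * b$value, ag_any_grad(a, b))
  av <- a$value; bv <- b$value
  ag_record(out, list(a, b), function(g) list(g * bv, g * av))
}

ag_sum <- function(a) {
  out <- ag_tensor(sum(a$value), a$requires_grad)
  d <- dim(a$value) %||% length(a$value)
  ag_record(out, list(a), function(g) list(array(g, d)))
}

# Combined soft-Dice + binary cross-entropy loss on logits, with an analytic
# backward pass (numerically stable log-sigmoid for the BCE term).
ag_dice_bce_loss <- function(logits, target, eps = 1e-5) {
  z <- logits$value
  t <- as.numeric(target)
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  # BCE with logits: mean over voxels
  bce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  sp <- sum(p); st <- sum(t); spt <- sum(p * t)
  denom <- sp + st + eps
  dice <- (2 * spt + eps) / denom
  loss <- (1 - dice) + bce
  out <- ag_tensor(loss, logits$requires_grad)
  ag_record(out, list(logits), function(g) {
    dp <- -(2 * t * denom - (2 * spt + eps)) / denom^2   # d(1-dice)/dp
    dz_dice <- dp * p * (1 - p)
    dz_bce <- (p - t) / n
    dz <- g * (dz_dice + dz_bce)
    dim(dz) <- dim(z)
    list(dz)
  })
}
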