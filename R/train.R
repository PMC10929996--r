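# Training loop (Dice+BCE loss, SGD with Nesterov momentum and polynomial
# learning-rate decay, batch size 1, four random patches per volume per
# epoch) and whole-volume sliding-window inference.

#' Training configuration
#'
#' Defaults follow the training protocol of the network: stochastic gradient
#' descent from an initial learning rate of 1e-3 with batch size 1 and four
#' random 96^3 patches per volume per epoch. Momentum (0.99, Nesterov),
#' weight decay (3e-5), polynomial decay (power 0.9), and gradient clipping
#' (norm 12) are the package's own choices where the protocol is silent.
#'
#' @param epochs one epoch is one pass over the training volumes (four
#'   patch-steps each).
#' @param initial_lr initial SGD learning rate.
#' @param batch_size training batch size (1).
#' @param patches_per_volume random patches sampled per volume per epoch.
#' @param patch_size patch edge length in voxels.
#' @param fg_fraction foreground-biased sampling probability.
#' @param loss `"dice_bce"`, `"dice"`, or `"bce"`.
#' @param momentum,nesterov,weight_decay,clip_norm optimizer settings.
#' @param lr_power polynomial decay exponent.
#' @param val_fraction fraction of cases held out for validation (by case,
#'   seeded); 0 disables validation.
#' @param eval_interval epochs between validation / monitor evaluations.
#' @param stop_train_dice optional early-stop target: stop once the mean
#'   training-set Dice reaches this value (checked every `eval_interval`).
#' @param augment an [augment_config()], or `NULL` for no augmentation.
#' @param seed master seed for the split, sampling, and augmentation.
#' @export
train_config <- function(epochs = 1000L, initial_lr = 1e-3, batch_size = 1L,
                         patches_per_volume = 4L, patch_size = 96L,
                         fg_fraction = 0.5, loss = "dice_bce",
                         momentum = 0.99, nesterov = TRUE,
                         weight_decay = 3e-5, clip_norm = 12,
                         lr_power = 0.9, val_fraction = 0.1,
                         eval_interval = 5L, stop_train_dice = NULL,
                         augment = augment_config(), seed = 1L) {
  stopifnot(epochs >= 0L, batch_size >= 1L, initial_lr > 0)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 patch_size = as.integer(patch_size),
                 fg_fraction = fg_fraction, loss = loss,
                 momentum = momentum, nesterov = isTRUE(nesterov),
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 lr_power = lr_power, val_fraction = val_fraction,
                 eval_interval = as.integer(eval_interval),
                 stop_train_dice = stop_train_dice,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Segmentation loss
#'
#' Default: soft Dice (on sigmoid probabilities, with a small smoothing
#' constant) plus voxel-mean binary cross-entropy -- the standard pairing for
#' heavily class-imbalanced volumetric segmentation, with the Dice metric as
#' the optimization surrogate.
#'
#' @param logits real-valued score array.
#' @param target aligned binary mask (array or `seg_mask`).
#' @param kind `"dice_bce"` (default), `"dice"`, or `"bce"`.
#' @return scalar loss.
#' @export
compute_loss <- function(logits, target, kind = "dice_bce") {
  t <- as.numeric(mask_array(target))
  z <- as.numeric(logits)
  if (length(z) != length(t)) stop("logits/target shape mismatch")
  p <- 1 / (1 + exp(-z))
  bce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  eps <- 1e-5
  dice <- (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  switch(kind,
         dice_bce = (1 - dice) + bce,
         dice = 1 - dice,
         bce = bce,
         stop("unknown loss kind: ", kind))
}

# SGD with Nesterov momentum, weight decay, and global-norm gradient
# clipping. `flat` is the flattened parameter list; `state` holds velocity.
sgd_step <- function(flat, state, lr, cfg) {
  gn2 <- 0
  for (t in flat) if (!is.null(t$grad)) gn2 <- gn2 + sum(t$grad^2)
  gscale <- if (cfg$clip_norm > 0 && sqrt(gn2) > cfg$clip_norm)
    cfg$clip_norm / sqrt(gn2) else 1
  for (nm in names(flat)) {
    t <- flat[[nm]]
    if (is.null(t$grad)) next
    g <- t$grad * gscale + cfg$weight_decay * t$value
    v <- state[[nm]] %||% 0
    v <- cfg$momentum * v + g
    step <- if (cfg$nesterov) g + cfg$momentum * v else v
    t$value <- t$value - lr * step
    state[[nm]] <- v
    t$grad <- NULL
  }
  state
}

model_from_checkpoint <- function(ckpt) {
  m <- coretr_model(ckpt$model_cfg, seed = 0L)
  params_load_values(m$params, ckpt$weights)
  m
}

make_checkpoint <- function(model, cfg, epoch, best_val_dice, history) {
  structure(list(weights = params_values(model$params),
                 model_cfg = model$config, train_cfg = cfg,
                 epoch = epoch, best_val_dice = best_val_dice,
                 history = history,
                 rng_state = get0(".Random.seed", envir = globalenv())),
            class = "coretr_checkpoint")
}

#' Save / load a training checkpoint
#'
#' A checkpoint carries every parameter value, the config snapshot, the
#' epoch, the RNG state, and the best validation Dice; reloading restores
#' bit-identical forward outputs.
#'
#' @param ckpt a `coretr_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

mean_dice_on <- function(model, cases, patch_size, overlap = 0.25) {
  mean(vapply(cases, function(cs) {
    pred <- sliding_window_predict(cs$volume, model, patch = patch_size,
                                   overlap = overlap)
    dice_score(pred, cs$mask)
  }, numeric(1)))
}

#' Train a model
#'
#' Per epoch and per training volume: sample `patches_per_volume` random
#' patches (foreground-biased), augment, and take one SGD step per patch
#' (batch size 1) on the Dice+BCE loss. Logs per-epoch mean loss and, every
#' `eval_interval` epochs, the validation Dice (sliding-window inference on
#' the held-out cases); the checkpoint with the best validation Dice is
#' returned (the final one when there is no validation split). A NaN loss
#' aborts with a diagnostic error.
#'
#' @param dataset list of cases, each a list with `volume` (normalized
#'   `ct_volume`) and `mask` (`seg_mask`) -- e.g. from [phantom_dataset()]
#'   after preprocessing.
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()]; its `patch_size` should match
#'   `cfg$patch_size`.
#' @param model optionally, a warm-start [coretr_model()].
#' @param verbose print per-epoch progress.
#' @return a `coretr_checkpoint` (with a `history` tibble of epoch, lr,
#'   mean loss, and monitor Dice values).
#' @export
train <- function(dataset, cfg = train_config(), model_cfg = model_config(),
                  model = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)

  if (is.null(model)) model <- coretr_model(model_cfg, seed = cfg$seed)
  flat <- params_flatten(model$params, "p")
  state <- list()

  n <- length(dataset)
  n_val <- if (cfg$val_fraction > 0 && n >= 2L)
    max(1L, floor(cfg$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) stop("no training cases left after split")

  best <- list(dice = -Inf, ckpt = NULL)
  hist <- list()
  epoch <- 0L
  if (cfg$epochs > 0L) for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$initial_lr * (1 - (epoch - 1) / cfg$epochs)^cfg$lr_power
    losses <- c()
    for (ci in sample(train_idx)) {
      cs <- dataset[[ci]]
      patches <- crop_random_patches(cs$volume, cs$mask,
                                     size = cfg$patch_size,
                                     n = cfg$patches_per_volume,
                                     fg_fraction = cfg$fg_fraction)
      for (pt in patches) {
        if (!is.null(cfg$augment))
          pt <- apply_augmentations(pt, cfg$augment)
        x <- ag_tensor(array(pt$image, c(dim(pt$image), 1L)))
        loss <- ag_with_tape({
          logits <- coretr_forward_ag(model, x)
          ag_dice_bce_loss(logits, pt$mask)
        })
        if (!is.finite(loss$value))
          stop("training diverged: non-finite loss at epoch ", epoch)
        ag_backward(loss)
        state <- sgd_step(flat, state, lr, cfg)
        losses <- c(losses, loss$value)
      }
    }
    monitor <- NA_real_
    if (epoch %% cfg$eval_interval == 0L || epoch == cfg$epochs) {
      if (n_val > 0L) {
        monitor <- mean_dice_on(model, dataset[val_idx], cfg$patch_size)
        if (monitor >= best$dice) {
          best$dice <- monitor
          best$ckpt <- make_checkpoint(model, cfg, epoch, monitor, NULL)
        }
      } else if (!is.null(cfg$stop_train_dice)) {
        monitor <- mean_dice_on(model, dataset[train_idx], cfg$patch_size)
      }
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    loss = mean(losses), monitor = monitor)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f lr %.2e%s", epoch, mean(losses),
                      lr, ifelse(is.na(monitor), "",
                                 sprintf(" dice %.3f", monitor))))
    if (!is.null(cfg$stop_train_dice) && !is.na(monitor) &&
        monitor >= cfg$stop_train_dice) break
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    tibble::tibble(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                   monitor = numeric(0))
  out <- if (n_val > 0L && !is.null(best$ckpt)) {
    best$ckpt$history <- history
    best$ckpt
  } else make_checkpoint(model, cfg, epoch, best$dice, history)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Whole-volume sliding-window inference
#'
#' Tiles a preprocessed volume with overlapping cubic windows, averages the
#' sigmoid probabilities where windows overlap (seam-free for consistent
#' predictions), and thresholds at 0.5. Volumes smaller than the window are
#' zero-padded symmetrically and cropped back.
#'
#' @param vol normalized `ct_volume`.
#' @param model a `coretr_model` or `coretr_checkpoint`.
#' @param patch window edge length (defaults to the model's patch size).
#' @param overlap fractional overlap between adjacent windows in `[0, 1)`.
#' @param threshold probability threshold for binarization.
#' @return a `seg_mask` aligned to `vol`.
#' @export
sliding_window_predict <- function(vol, model, patch = NULL, overlap = 0.5,
                                   threshold = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!vol$normalized)
    coretr_error("coretr_error_unnormalized",
                 "volume must be preprocessed (truncate + normalize) first")
  if (inherits(model, "coretr_checkpoint")) model <- model_from_checkpoint(model)
  if (is.null(patch)) patch <- model$config$patch_size

  d0 <- dim(vol$voxels)
  pad_lo <- pmax(0L, (patch - d0 + 1L) %/% 2L)
  pad_hi <- pmax(0L, patch - d0 - pad_lo)
  d <- d0 + pad_lo + pad_hi
  img <- array(0, d)
  img[pad_lo[1] + seq_len(d0[1]), pad_lo[2] + seq_len(d0[2]),
      pad_lo[3] + seq_len(d0[3])] <- vol$voxels

  stride <- max(1L, as.integer(round(patch * (1 - overlap))))
  starts <- lapply(1:3, function(a) {
    s <- unique(pmin(seq(0L, max(0L, d[a] - patch), by = stride),
                     d[a] - patch))
    if (s[length(s)] != d[a] - patch) s <- c(s, d[a] - patch)
    unique(s)
  })
  prob <- array(0, d)
  cnt <- array(0, d)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    sel <- list(sx + seq_len(patch), sy + seq_len(patch), sz + seq_len(patch))
    tile <- img[sel[[1]], sel[[2]], sel[[3]]]
    logits <- coretr_forward(model, tile)
    prob[sel[[1]], sel[[2]], sel[[3]]] <-
      prob[sel[[1]], sel[[2]], sel[[3]]] + 1 / (1 + exp(-logits))
    cnt[sel[[1]], sel[[2]], sel[[3]]] <-
      cnt[sel[[1]], sel[[2]], sel[[3]]] + 1
  }
  prob <- prob / cnt
  m <- (prob >= threshold) * 1L
  m <- m[pad_lo[1] + seq_len(d0[1]), pad_lo[2] + seq_len(d0[2]),
         pad_lo[3] + seq_len(d0[3])]
  seg_mask(m, vol$spacing, vol$origin)
}
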