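# Evaluation metrics: Dice overlap, (percentile) Hausdorff distance in
# physical coordinates, connected-component analysis, and the single- versus
# multiple-tumor evaluation split with per-lesion reporting.

mask_array <- function(m) {
  if (inherits(m, "seg_mask")) m$voxels else {
    v <- as.integer(round(m)); dim(v) <- dim(m); v
  }
}

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)` between a predicted and a reference
#' mask. Two empty masks are in perfect agreement, so that case is defined
#' as 1; an empty prediction against a non-empty reference scores 0.
#'
#' @param pred,gt aligned binary masks (`seg_mask` or arrays).
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  p <- mask_array(pred); g <- mask_array(gt)
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0L) return(1)
  2 * sum(p & g) / (sp + sg)
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance over foreground voxel centres in physical
#' coordinates: `max(h(pred, gt), h(gt, pred))`, where the directed term
#' `h(A, B)` is the maximum (or, for `percentile < 1`, that percentile) of
#' the nearest-neighbour distances from A's foreground voxels to B's.
#' Distances come from an exact anisotropic Euclidean distance transform.
#'
#' @param pred,gt aligned binary masks.
#' @param spacing voxel spacing in mm; use `c(1, 1, 1)` for voxel units.
#' @param percentile 1 for the classical maximum; 0.95 for HD95.
#' @return distance in mm (or voxel units), or `NA` (with a warning) when
#'   either mask is empty -- the distance is undefined there, and an `NA`
#'   keeps it out of aggregate means instead of silently polluting them.
#' @export
hausdorff_distance <- function(pred, gt, spacing = c(1, 1, 1),
                               percentile = 1) {
  p <- mask_array(pred); g <- mask_array(gt)
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            percentile > 0, percentile <= 1)
  if (sum(p) == 0L || sum(g) == 0L) {
    warning("Hausdorff distance undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  dg <- sqrt(.cpp_edt_sq(g, dim(g), spacing))   # distance to gt
  dp <- sqrt(.cpp_edt_sq(p, dim(p), spacing))   # distance to pred
  d_p2g <- dg[p == 1L]
  d_g2p <- dp[g == 1L]
  stat <- function(d) if (percentile >= 1) max(d)
                      else as.numeric(stats::quantile(d, percentile))
  max(stat(d_p2g), stat(d_g2p))
}

#' Connected components of a mask (6-connectivity)
#'
#' @param mask binary mask.
#' @return integer array of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  m <- mask_array(mask)
  .cpp_label6(m, dim(m))
}

#' Score a case with the single-/multiple-tumor split
#'
#' Counts 6-connected components of the reference mask, classifies the case
#' (`"single"` / `"multiple"`), and computes global Dice, Hausdorff, and
#' HD95. For multiple tumors, predicted components are matched to reference
#' components by maximal voxel overlap (unmatched predicted components are
#' counted but not matched) and per-lesion metrics are reported.
#'
#' @param pred,gt aligned binary masks.
#' @param spacing voxel spacing in mm.
#' @return a `coretr_metrics` list: `dice`, `hd`, `hd95`,
#'   `n_components_gt`, `n_components_pred`, `category`, and `per_lesion`
#'   (tibble, or `NULL` for single-tumor cases).
#' @export
split_and_score <- function(pred, gt, spacing = c(1, 1, 1)) {
  p <- mask_array(pred); g <- mask_array(gt)
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  lg <- .cpp_label6(g, dim(g))
  lp <- .cpp_label6(p, dim(p))
  ng <- max(lg); np <- max(lp)
  both <- sum(p) > 0L && sum(g) > 0L
  res <- list(dice = dice_score(p, g),
              hd = if (both) hausdorff_distance(p, g, spacing) else NA_real_,
              hd95 = if (both) hausdorff_distance(p, g, spacing, 0.95)
                     else NA_real_,
              n_components_gt = ng,
              n_components_pred = np,
              category = if (ng > 1L) "multiple" else "single",
              per_lesion = NULL)
  if (ng > 1L) {
    # match predicted components to gt components by maximal overlap
    assign_to <- integer(np)
    for (k in seq_len(np)) {
      ov <- tabulate(lg[lp == k], nbins = ng)
      assign_to[k] <- if (any(ov > 0L)) which.max(ov) else 0L
    }
    rows <- lapply(seq_len(ng), function(i) {
      gi <- array((lg == i) * 1L, dim(g))
      pi_ <- array((lp %in% which(assign_to == i)) * 1L, dim(p))
      ok <- sum(pi_) > 0L
      tibble::tibble(
        lesion = i,
        gt_voxels = sum(gi),
        pred_voxels = sum(pi_),
        dice = dice_score(pi_, gi),
        hd = if (ok) hausdorff_distance(pi_, gi, spacing) else NA_real_,
        hd95 = if (ok) hausdorff_distance(pi_, gi, spacing, 0.95)
               else NA_real_)
    })
    res$per_lesion <- do.call(rbind, rows)
  }
  class(res) <- "coretr_metrics"
  res
}

#' @export
print.coretr_metrics <- function(x, ...) {
  cat(sprintf("<coretr_metrics> %s-tumor case: Dice %.4f, HD %s, HD95 %s\n",
              x$category, x$dice,
              ifelse(is.na(x$hd), "NA", sprintf("%.3f", x$hd)),
              ifelse(is.na(x$hd95), "NA", sprintf("%.3f", x$hd95))))
  if (!is.null(x$per_lesion)) print(x$per_lesion)
  invisible(x)
}

#' Evaluate a set of prediction/reference pairs
#'
#' @param preds,gts lists of aligned masks.
#' @param spacing voxel spacing (shared, or a list per case).
#' @return tibble with one row per case plus Dice/HD summaries; the
#'   aggregate is the unweighted mean over cases.
#' @export
evaluate_cases <- function(preds, gts, spacing = c(1, 1, 1)) {
  stopifnot(length(preds) == length(gts))
  rows <- lapply(seq_along(preds), function(i) {
    sp <- if (is.list(spacing)) spacing[[i]] else spacing
    m <- split_and_score(preds[[i]], gts[[i]], sp)
    tibble::tibble(case = i, category = m$category, dice = m$dice,
                   hd = m$hd, hd95 = m$hd95,
                   n_components_gt = m$n_components_gt,
                   n_components_pred = m$n_components_pred)
  })
  do.call(rbind, rows)
}
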