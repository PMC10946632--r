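#' Segmentation evaluation metrics
#'
#' Voxel-overlap metrics (Dice, sensitivity, specificity) from a confusion
#' tally, and surface-distance metrics: the 95th-percentile Hausdorff
#' distance (Haus95) and the average boundary displacement (ABD), both
#' symmetric over the two mask surfaces. Surfaces are the mask voxels with
#' at least one of their 6 face-neighbours outside the mask (voxels on the
#' grid border count as boundary). Distances are reported in mm by scaling
#' voxel coordinates with the spacing; metrics that are undefined (an empty
#' mask) return `NA` rather than a silent zero.
#'
#' @name seg_metrics
NULL

#' Voxelwise confusion counts between two binary masks
#'
#' @param pred,truth binary arrays of identical shape.
#' @return a list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot_same_shape(pred, truth, "pred and truth")
  p <- pred != 0
  t <- truth != 0
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

#' Dice score from confusion counts: 2TP / (FP + 2TP + FN)
#'
#' Both masks empty is a perfect (if vacuous) agreement and returns 1.
#' @param c confusion counts from [confusion_counts()].
#' @return the Dice score in `[0, 1]`.
#' @export
dice_score <- function(c) {
  den <- c$fp + 2 * c$tp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Sensitivity TP / (TP + FN)
#' @param c confusion counts.
#' @return sensitivity, or `NA` when the truth mask is empty.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) return(NA_real_)
  c$tp / den
}

#' Specificity TN / (FP + TN)
#' @param c confusion counts.
#' @return specificity, or `NA` when there are no negative voxels.
#' @export
specificity <- function(c) {
  den <- c$fp + c$tn
  if (den == 0) return(NA_real_)
  c$tn / den
}

#' Extract the boundary voxels of a binary mask as surface points
#'
#' A boundary voxel has at least one of its 6 face-neighbours outside the
#' mask (out-of-grid counts as outside).
#'
#' @param mask binary 3-D array.
#' @param spacing voxel size (mm); points are returned in mm coordinates
#'   (voxel index times spacing).
#' @return an `n x 3` matrix of surface point coordinates (mm); zero rows
#'   for an empty mask.
#' @export
surface_points <- function(mask, spacing = c(1, 1, 1)) {
  m <- mask != 0
  d <- dim(m)
  if (!any(m)) return(matrix(numeric(0), 0, 3))
  pad <- array(FALSE, d + 2L)
  pad[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- m
  i1 <- seq_len(d[1]) + 1L; i2 <- seq_len(d[2]) + 1L; i3 <- seq_len(d[3]) + 1L
  allin <- pad[i1 - 1L, i2, i3] & pad[i1 + 1L, i2, i3] &
    pad[i1, i2 - 1L, i3] & pad[i1, i2 + 1L, i3] &
    pad[i1, i2, i3 - 1L] & pad[i1, i2, i3 + 1L]
  boundary <- m & !allin
  idx <- which(boundary, arr.ind = TRUE)
  sweep(matrix(as.numeric(idx), ncol = 3), 2, as.numeric(spacing), "*")
}

percentile_linear <- function(x, p) {
  # linear-interpolation percentile (R type 7), stated for reproducibility
  as.numeric(quantile(x, probs = p, type = 7, names = FALSE))
}

#' 95th-percentile Hausdorff distance between two surface point sets
#'
#' The maximum over both directions of the 95th percentile
#' (linear-interpolation) of nearest-neighbour distances from one set to
#' the other.
#'
#' @param x,y `n x 3` matrices of surface points (same units).
#' @return the Haus95 distance, or `NA` if either set is empty.
#' @export
hausdorff95 <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(NA_real_)
  dxy <- percentile_linear(rx_min_dists(x, y), 0.95)
  dyx <- percentile_linear(rx_min_dists(y, x), 0.95)
  max(dxy, dyx)
}

#' Average boundary displacement between two surface point sets
#'
#' `(sum of nearest-neighbour distances x -> y + sum y -> x) / (|x| + |y|)`.
#'
#' @param x,y `n x 3` matrices of surface points.
#' @return the ABD, or `NA` if either set is empty.
#' @export
average_boundary_distance <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(NA_real_)
  (sum(rx_min_dists(x, y)) + sum(rx_min_dists(y, x))) / (nrow(x) + nrow(y))
}

#' Evaluate all five metrics per tumor subregion
#'
#' @param pred,truth `region_channels` objects of identical shape.
#' @param spacing voxel size in mm; surface distances are reported in mm.
#' @return a data frame with one row per region (wt, tc, et) and columns
#'   dice, sensitivity, specificity, haus95_mm, abd_mm.
#' @export
evaluate_case <- function(pred, truth, spacing = c(1, 1, 1)) {
  rows <- lapply(region_names(), function(r) {
    p <- pred[[r]]
    t <- truth[[r]]
    stopifnot_same_shape(p, t, sprintf("region %s", r))
    cc <- confusion_counts(p, t)
    sp_p <- surface_points(p, spacing)
    sp_t <- surface_points(t, spacing)
    data.frame(region = r,
               dice = dice_score(cc),
               sensitivity = sensitivity(cc),
               specificity = specificity(cc),
               haus95_mm = hausdorff95(sp_p, sp_t),
               abd_mm = average_boundary_distance(sp_p, sp_t),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
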