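#' Three-dimensional shape features (14) of a binary mask
#'
#' Surface Area and Mesh Volume come from a closed triangle mesh extracted
#' from the binary mask by marching tetrahedra at iso-level 0.5 (vertices on
#' voxel-centre edges, spacing-aware); the signed mesh volume uses the
#' divergence theorem. Sphericity is `pi^(1/3) * (6V)^(2/3) / A`. Axis
#' lengths derive from the principal-component eigenvalues `l` of the
#' physical coordinates of the mask voxels (`4 * sqrt(l)`), with
#' `Elongation = sqrt(l2/l1)` and `Flatness = sqrt(l3/l1)`. Maximum 2D
#' diameters are the largest pairwise boundary-voxel distances within
#' constant-z (Slice), constant-y (Row) and constant-x (Column) planes;
#' the Maximum 3D diameter is the largest over all boundary pairs.
#'
#' @param mask binary 3-D array (nonempty).
#' @param spacing voxel size in mm.
#' @return named numeric vector of 14 shape features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  msk <- (mask != 0) * 1L
  if (!any(msk == 1L))
    radsurv_abort("mask is empty", "radsurv_error_validation")
  # mesh a box-smoothed indicator so interpolated crossings approximate the
  # underlying smooth boundary instead of the voxel staircase; fall back to
  # the raw indicator (midpoint crossings) for structures so thin that
  # smoothing would drop them below the iso level
  field <- box_mean3(msk)
  if (!any(field > 0.5)) field <- msk
  tri <- rx_surface_mesh(as.numeric(field), dim(msk))
  # scale voxel coordinates (0-based centres) to mm
  v1 <- sweep(tri[, 1:3, drop = FALSE], 2, spacing, "*")
  v2 <- sweep(tri[, 4:6, drop = FALSE], 2, spacing, "*")
  v3 <- sweep(tri[, 7:9, drop = FALSE], 2, spacing, "*")
  e1 <- v2 - v1
  e2 <- v3 - v1
  crx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(crx^2))) / 2
  # signed volume: sum of v1 . (v2 x v3) / 6 over outward-oriented triangles
  cr23 <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
                v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
                v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  volume <- abs(sum(rowSums(v1 * cr23))) / 6
  nv <- sum(msk)
  vox_vol <- nv * prod(spacing)
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area

  idx <- which(msk == 1L, arr.ind = TRUE)
  phys <- sweep(matrix(as.numeric(idx), ncol = 3), 2, as.numeric(spacing),
                "*")
  ev <- if (nrow(phys) > 1) {
    eigen(stats::cov(phys), symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axis_len <- 4 * sqrt(ev)

  bp <- surface_points(msk, spacing)
  max2d <- function(fix_ax) {
    plane_ax <- setdiff(1:3, fix_ax)
    best <- 0
    for (u in unique(bp[, fix_ax])) {
      q <- bp[bp[, fix_ax] == u, plane_ax, drop = FALSE]
      if (nrow(q) > 1) best <- max(best, max_pairwise_dist(q))
    }
    best
  }
  c(
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    LeastAxisLength = axis_len[3],
    MajorAxisLength = axis_len[1],
    Maximum2DDiameterColumn = max2d(1L),
    Maximum2DDiameterRow = max2d(2L),
    MeshVolume = volume,
    MinorAxisLength = axis_len[2],
    Sphericity = sphericity,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / volume,
    VoxelVolume = vox_vol,
    Maximum2DDiameterSlice = max2d(3L),
    Maximum3DDiameter = max_pairwise_dist(bp)
  )
}

shape_feature_names <- function() c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MeshVolume",
  "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
  "VoxelVolume", "Maximum2DDiameterSlice", "Maximum3DDiameter")

box_mean3 <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- m
  out <- array(0, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2)
    out <- out + pad[dx + seq_len(d[1]), dy + seq_len(d[2]),
                     dz + seq_len(d[3])]
  out / 27
}

# largest pairwise Euclidean distance, chunked to bound memory
max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  step <- 512L
  sq <- rowSums(pts^2)
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[s:e], rep(0, n), "+") + matrix(sq, e - s + 1L, n,
                                                  byrow = TRUE) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(pmax(best, 0))
}
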