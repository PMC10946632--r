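#' Configuration for radiomic feature extraction
#'
#' Exactly one of `bin_width` / `fixed_bin_count` controls intensity
#' discretization. `bin_width` (default 25 intensity units) suits raw
#' scanner intensities; `fixed_bin_count` is preferable after z-score
#' normalization, where absolute bin widths are fragile.
#'
#' @param bin_width fixed bin width in intensity units, or `NULL`.
#' @param fixed_bin_count fixed number of equal-width bins over the in-mask
#'   range, or `NULL`.
#' @param glcm_distance co-occurrence offset length in voxels (default 1).
#' @param gldm_alpha dependence threshold on the absolute level difference
#'   (default 0).
#' @param wavelet wavelet family for the sub-band images; `"db4"` (8-tap
#'   orthogonal Daubechies) is the only built-in.
#' @param wavelet_level decomposition level; fixed at 1.
#' @return a `feature_config` list.
#' @export
feature_config <- function(bin_width = NULL, fixed_bin_count = NULL,
                           glcm_distance = 1L, gldm_alpha = 0L,
                           wavelet = "db4", wavelet_level = 1L) {
  if (is.null(bin_width) && is.null(fixed_bin_count)) bin_width <- 25
  if (!is.null(bin_width) && !is.null(fixed_bin_count))
    radsurv_abort("set exactly one of bin_width / fixed_bin_count",
                  "radsurv_error_config")
  if (!is.null(bin_width) && bin_width <= 0)
    radsurv_abort("bin_width must be positive", "radsurv_error_config")
  if (!is.null(fixed_bin_count) && fixed_bin_count < 1)
    radsurv_abort("fixed_bin_count must be >= 1", "radsurv_error_config")
  if (wavelet_level != 1L)
    radsurv_abort("only single-level wavelet decomposition is supported",
                  "radsurv_error_config")
  structure(list(bin_width = bin_width, fixed_bin_count = fixed_bin_count,
                 glcm_distance = as.integer(glcm_distance),
                 gldm_alpha = as.integer(gldm_alpha), wavelet = wavelet,
                 wavelet_level = 1L),
            class = "feature_config")
}

#' Discretize the in-mask intensities of a region of interest
#'
#' Fixed-bin-width mode assigns level `floor((x - min) / w) + 1`; fixed-bin
#' -count mode uses `Ng` equal-width bins over the in-mask range with the
#' maximum intensity mapped to level `Ng`. A zero intensity range yields a
#' single level.
#'
#' @param image numeric 3-D array.
#' @param mask binary array of the same shape (nonempty).
#' @param cfg a [feature_config()].
#' @return a `discretized_roi`: integer `levels` array (0 outside the
#'   mask), `mask`, `Ng`, and `bin_edges`.
#' @export
discretize_roi <- function(image, mask, cfg = feature_config()) {
  stopifnot_same_shape(image, mask, "image and mask")
  msk <- mask != 0
  if (!any(msk))
    radsurv_abort("mask is empty", "radsurv_error_validation")
  v <- image[msk]
  rng <- range(v)
  lev <- array(0L, dim(image))
  if (rng[2] - rng[1] <= 0) {
    lev[msk] <- 1L
    ng <- 1L
    edges <- rng
  } else if (!is.null(cfg$bin_width)) {
    w <- cfg$bin_width
    li <- floor((v - rng[1]) / w) + 1
    ng <- as.integer(max(li))
    lev[msk] <- as.integer(li)
    edges <- rng[1] + w * (0:ng)
  } else {
    ng <- as.integer(cfg$fixed_bin_count)
    w <- (rng[2] - rng[1]) / ng
    li <- pmin(floor((v - rng[1]) / w) + 1, ng)  # max maps to Ng
    lev[msk] <- as.integer(li)
    edges <- seq(rng[1], rng[2], length.out = ng + 1)
  }
  structure(list(levels = lev, mask = msk, Ng = ng, bin_edges = edges),
            class = "discretized_roi")
}

#' The 13 unique non-antipodal 3-D neighbourhood directions
#' @return a 13 x 3 integer matrix of voxel offsets.
#' @export
texture_directions <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(m) <- "integer"
  m
}
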