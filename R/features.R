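#' Interpolated statistics (9) of a region of interest
#'
#' Acquisition- and geometry-level descriptors: voxel spacing, the mask
#' bounding box, voxel count, connected-volume count (26-connected), centre
#' of mass in voxel-index and world (mm) units, and the in-mask intensity
#' mean/minimum/maximum. Multi-component statistics are expanded into
#' suffixed scalar entries.
#'
#' @param image numeric 3-D array.
#' @param mask binary array of the same shape (nonempty).
#' @param spacing voxel size in mm.
#' @return named numeric vector (20 scalars expanding the 9 statistics).
#' @export
interpolated_statistics <- function(image, mask, spacing = c(1, 1, 1)) {
  msk <- mask != 0
  if (!any(msk))
    radsurv_abort("mask is empty", "radsurv_error_validation")
  idx <- which(msk, arr.ind = TRUE)
  v <- image[msk]
  com_idx <- unname(colMeans(idx))
  zs <- rx_zone_sizes(array(as.integer(msk), dim(msk)), dim(msk))
  c(
    Spacing_x = spacing[1], Spacing_y = spacing[2], Spacing_z = spacing[3],
    BoundingBox_x0 = min(idx[, 1]), BoundingBox_y0 = min(idx[, 2]),
    BoundingBox_z0 = min(idx[, 3]),
    BoundingBox_dx = diff(range(idx[, 1])) + 1,
    BoundingBox_dy = diff(range(idx[, 2])) + 1,
    BoundingBox_dz = diff(range(idx[, 3])) + 1,
    VoxelNum = sum(msk),
    VolumeNum = nrow(zs),
    CenterOfMassIndex_x = com_idx[1], CenterOfMassIndex_y = com_idx[2],
    CenterOfMassIndex_z = com_idx[3],
    CenterOfMass_x = com_idx[1] * spacing[1],
    CenterOfMass_y = com_idx[2] * spacing[2],
    CenterOfMass_z = com_idx[3] * spacing[3],
    Mean = mean(v), Minimum = min(v), Maximum = max(v)
  )
}

interp_stat_names <- function() c(
  "Spacing", "BoundingBox", "VoxelNum", "VolumeNum", "CenterOfMassIndex",
  "CenterOfMass", "Mean", "Minimum", "Maximum")

#' The radiomic feature registry
#'
#' One row per feature name, by category, mirroring the implemented bank:
#' shape (14), first order (18), GLCM (22), GLRLM (16), GLSZM (16), GLDM
#' (14) and interpolated statistics (9).
#'
#' @return a data frame with columns `category` and `name`.
#' @export
feature_registry <- function() {
  cats <- list(
    shape = shape_feature_names(),
    firstorder = first_order_feature_names(),
    glcm = glcm_feature_names(),
    glrlm = glrlm_feature_names(),
    glszm = glszm_feature_names(),
    gldm = gldm_feature_names(),
    interpstat = interp_stat_names()
  )
  do.call(rbind, lapply(names(cats), function(k)
    data.frame(category = k, name = cats[[k]], stringsAsFactors = FALSE)))
}

texture_block <- function(image, mask, cfg, spacing) {
  roi <- discretize_roi(image, mask, cfg)
  c(
    setNames(first_order_features(image, mask, cfg, spacing),
             paste0("firstorder_", first_order_feature_names())),
    setNames(glcm_features(roi, cfg), paste0("glcm_", glcm_feature_names())),
    setNames(glrlm_features(roi, cfg),
             paste0("glrlm_", glrlm_feature_names())),
    setNames(glszm_features(roi, cfg),
             paste0("glszm_", glszm_feature_names())),
    setNames(gldm_features(roi, cfg), paste0("gldm_", gldm_feature_names()))
  )
}

decimate_mask <- function(mask) {
  # 2^3-block union: a sub-band voxel is in the mask if any source voxel of
  # its block is (keeps nonempty masks nonempty)
  d <- dim(mask)
  m <- mask != 0
  arr <- array(m, dim = c(2, d[1] %/% 2, 2, d[2] %/% 2, 2, d[3] %/% 2))
  out <- apply(arr, c(2, 4, 6), any)
  out * 1L
}

#' Expected feature-vector length for a configuration
#'
#' `per image = 86` (18 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM +
#' 14 GLDM) on the original image and each of the 8 wavelet sub-bands,
#' plus 20 interpolated-statistic scalars on the original image, per
#' modality and region; plus 14 shape scalars per region.
#'
#' @param n_modalities number of modalities (default 4).
#' @param n_regions number of regions (default 3).
#' @return the expected number of entries of [extract_case_features()].
#' @export
feature_count <- function(n_modalities = 4L, n_regions = 3L) {
  per_image <- 18L + 22L + 16L + 16L + 14L
  n_modalities * n_regions * (per_image * 9L + 20L) + n_regions * 14L
}

#' Extract the full radiomic feature vector for one case
#'
#' For every modality and region: first-order and the four texture families
#' on the original image and on each of the 8 wavelet sub-bands, plus
#' interpolated statistics on the original image; per region, the shape
#' block (mask-only, computed once). Names follow
#' `modality_region_image_category_feature` (shape entries use
#' `mask_region_shape_feature`). Ordering is deterministic. Features of an
#' empty region are emitted as `NA`.
#'
#' @param volume a `multimodal_volume` or a 4-channel array.
#' @param regions a `region_channels` object.
#' @param cfg a [feature_config()].
#' @param spacing voxel size in mm (taken from `volume` when available).
#' @return a named numeric vector of length [feature_count()].
#' @export
extract_case_features <- function(volume, regions,
                                  cfg = feature_config(fixed_bin_count = 32),
                                  spacing = NULL) {
  if (inherits(volume, "multimodal_volume")) {
    spacing <- spacing %||% volume$spacing
    data <- volume$data
  } else {
    spacing <- spacing %||% c(1, 1, 1)
    data <- volume
  }
  if (all(vapply(region_names(), function(r) !any(regions[[r]] != 0),
                 logical(1))))
    radsurv_abort("all regions are empty", "radsurv_error_validation")
  out <- numeric(0)
  band_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  per_image_names <- c(paste0("firstorder_", first_order_feature_names()),
                       paste0("glcm_", glcm_feature_names()),
                       paste0("glrlm_", glrlm_feature_names()),
                       paste0("glszm_", glszm_feature_names()),
                       paste0("gldm_", gldm_feature_names()))
  for (m in seq_len(4)) {
    mod <- RADSURV_MODALITIES[m]
    img <- data[, , , m]
    bands <- wavelet_bands(img)
    for (r in region_names()) {
      msk <- regions[[r]]
      empty <- !any(msk != 0)
      blk <- function(image, mask, sp, tag) {
        vals <- if (empty) {
          setNames(rep(NA_real_, length(per_image_names)), per_image_names)
        } else texture_block(image, mask, cfg, sp)
        setNames(vals, paste(mod, r, tag, names(vals), sep = "_"))
      }
      out <- c(out, blk(img, msk, spacing, "original"))
      if (!empty) {
        iv <- interpolated_statistics(img, msk, spacing)
      } else {
        iv <- setNames(rep(NA_real_, 20), names(interpolated_statistics(
          array(1, c(2, 2, 2)), array(1, c(2, 2, 2)))))
      }
      out <- c(out, setNames(iv, paste(mod, r, "original_interpstat",
                                       names(iv), sep = "_")))
      dm <- if (empty) NULL else decimate_mask(msk)
      for (b in band_names)
        out <- c(out, blk(bands[[b]], dm, spacing * 2,
                          paste0("wavelet.", b)))
    }
  }
  for (r in region_names()) {
    msk <- regions[[r]]
    sv <- if (any(msk != 0)) shape_features(msk, spacing) else
      setNames(rep(NA_real_, 14), shape_feature_names())
    out <- c(out, setNames(sv, paste("mask", r, "shape", names(sv),
                                     sep = "_")))
  }
  out
}

#' Extract features for a whole cohort into a wide table
#'
#' @param cases list of lists with elements `volume` and `regions` (or
#'   `labels`, which will be encoded).
#' @param cfg a [feature_config()].
#' @param case_ids optional character vector of identifiers.
#' @return a data frame, one row per case, first column `case_id`.
#' @export
extract_cohort_features <- function(cases,
                                    cfg = feature_config(
                                      fixed_bin_count = 32),
                                    case_ids = NULL) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    regions <- cs$regions %||% encode_regions(cs$labels)
    extract_case_features(cs$volume, regions, cfg)
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(case_id = case_ids %||% sprintf("case_%03d",
                                                   seq_along(cases)),
                   mat, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  df
}
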