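#' Multimodal volume constructors and NIfTI ingestion
#'
#' A `multimodal_volume` holds the four co-registered MRI sequences of one
#' case (T1, T1ce, T2, FLAIR) as a single 4-D array `[x, y, z, channel]`
#' together with voxel spacing (mm) and the voxel-to-world affine. A
#' `label_volume` holds the matching integer segmentation with the BraTS
#' label convention: 0 background, 1 necrotic/non-enhancing core, 2 edema,
#' 4 enhancing tumor.
#'
#' @name io_volumes
NULL

RADSURV_MODALITIES <- c("t1", "t1ce", "t2", "flair")
RADSURV_LABELS <- c(0L, 1L, 2L, 4L)

#' Construct a multimodal volume
#'
#' @param data numeric 4-D array `[x, y, z, 4]`, channel order T1, T1ce, T2,
#'   FLAIR.
#' @param spacing numeric length-3 voxel size in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to a scaling by
#'   `spacing`.
#' @return an object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 4 || dim(data)[4] != 4)
    radsurv_abort("multimodal volume needs a 4-D array with 4 channels",
                  "radsurv_error_validation")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    radsurv_abort("spacing must be 3 strictly positive values",
                  "radsurv_error_validation")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing),
                 modalities = RADSURV_MODALITIES, affine = affine),
            class = "multimodal_volume")
}

#' Construct a label volume
#'
#' @param labels integer 3-D array with values in \{0, 1, 2, 4\}.
#' @param spacing numeric length-3 voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(labels)) != 3)
    radsurv_abort("labels must be a 3-D array", "radsurv_error_validation")
  bad <- setdiff(unique(as.integer(labels)), RADSURV_LABELS)
  if (length(bad))
    radsurv_abort(
      sprintf("label volume contains disallowed values: %s",
              paste(bad, collapse = ", ")),
      "radsurv_error_validation")
  storage.mode(labels) <- "integer"
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 affine = affine),
            class = "label_volume")
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

#' Load one case from NIfTI files
#'
#' Reads the four modality images (fixed order T1, T1ce, T2, FLAIR) and an
#' optional label image, validating that all spatial shapes agree and that
#' labels use only the BraTS values \{0, 1, 2, 4\}.
#'
#' @param image_paths character vector of 4 NIfTI paths in the order T1,
#'   T1ce, T2, FLAIR (names, if present, are ignored; order is the contract).
#' @param label_path optional NIfTI path of the segmentation.
#' @return a list with elements `volume` (`multimodal_volume`) and `labels`
#'   (`label_volume` or `NULL`).
#' @export
load_case <- function(image_paths, label_path = NULL) {
  if (length(image_paths) != 4)
    radsurv_abort("exactly 4 modality paths required (t1, t1ce, t2, flair)",
                  "radsurv_error_validation")
  imgs <- lapply(image_paths, function(p) {
    if (!file.exists(p))
      radsurv_abort(sprintf("file not found: %s", p), "radsurv_error_io")
    RNifti::readNifti(p)
  })
  shp <- dim(imgs[[1]])[seq_len(3)]
  for (i in seq_along(imgs)) {
    di <- dim(imgs[[i]])[seq_len(3)]
    if (!identical(as.integer(di), as.integer(shp)))
      radsurv_abort(
        sprintf("shape mismatch in %s: %s vs %s", image_paths[i],
                paste(di, collapse = "x"), paste(shp, collapse = "x")),
        "radsurv_error_shape")
  }
  data <- array(0, dim = c(shp, 4))
  for (i in seq_len(4)) data[, , , i] <- as.array(imgs[[i]])
  vol <- multimodal_volume(data, spacing = nifti_spacing(imgs[[1]]),
                           affine = structure(RNifti::xform(imgs[[1]]),
                                              dimnames = NULL))
  lab <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path))
      radsurv_abort(sprintf("file not found: %s", label_path),
                    "radsurv_error_io")
    li <- RNifti::readNifti(label_path)
    dl <- dim(li)[seq_len(3)]
    if (!identical(as.integer(dl), as.integer(shp)))
      radsurv_abort(
        sprintf("shape mismatch in %s: %s vs %s", label_path,
                paste(dl, collapse = "x"), paste(shp, collapse = "x")),
        "radsurv_error_shape")
    arr <- as.array(li)
    if (any(abs(arr - round(arr)) > 1e-6))
      radsurv_abort("label image is not integer-valued",
                    "radsurv_error_validation")
    lab <- label_volume(array(as.integer(round(arr)), dim = dl),
                        spacing = nifti_spacing(li),
                        affine = structure(RNifti::xform(li),
                                           dimnames = NULL))
  }
  list(volume = vol, labels = lab)
}

#' Write a multimodal volume (one NIfTI per modality) or a label volume
#'
#' @param x a `multimodal_volume` or `label_volume`.
#' @param paths for a multimodal volume, 4 output paths (T1, T1ce, T2,
#'   FLAIR); for a label volume, a single path.
#' @return the paths, invisibly.
#' @export
save_volumes <- function(x, paths) {
  if (inherits(x, "multimodal_volume")) {
    if (length(paths) != 4)
      radsurv_abort("need 4 paths for a multimodal volume",
                    "radsurv_error_validation")
    for (i in seq_len(4)) {
      img <- RNifti::asNifti(x$data[, , , i])
      RNifti::pixdim(img) <- x$spacing
      RNifti::writeNifti(img, paths[i])
    }
  } else if (inherits(x, "label_volume")) {
    img <- RNifti::asNifti(x$labels)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, paths[1])
  } else {
    radsurv_abort("unsupported object", "radsurv_error_validation")
  }
  invisible(paths)
}

#' Z-score normalize each modality
#'
#' Per modality, subtracts the mean and divides by the population standard
#' deviation, by default computed over the nonzero (brain) voxels only so
#' that the dominant zero background does not flatten tissue contrast;
#' background voxels stay exactly zero. With `support = "all"` statistics
#' are taken over the whole grid and every voxel is transformed.
#'
#' @param vol a `multimodal_volume`.
#' @param support `"nonzero"` (default) or `"all"`.
#' @return the normalized `multimodal_volume`.
#' @export
zscore_normalize <- function(vol, support = c("nonzero", "all")) {
  support <- match.arg(support)
  out <- vol$data
  for (m in seq_len(4)) {
    ch <- vol$data[, , , m]
    sel <- if (support == "nonzero") ch != 0 else rep(TRUE, length(ch))
    v <- ch[sel]
    if (!length(v))
      radsurv_abort(sprintf("modality %s has empty support",
                            vol$modalities[m]), "radsurv_error_degenerate")
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))  # population sd
    if (s < .Machine$double.eps * max(1, abs(mu)))
      radsurv_abort(sprintf("modality %s has zero intensity scale",
                            vol$modalities[m]), "radsurv_error_degenerate")
    chn <- ch
    chn[sel] <- (v - mu) / s
    if (support == "nonzero") chn[!sel] <- 0
    out[, , , m] <- chn
  }
  vol$data <- out
  vol
}

#' Crop a case to a fixed-side training patch
#'
#' Centres a cubic patch (default side 128) on the centre of the lesion
#' bounding box, clamps it to the volume bounds, and zero-pads where the
#' source volume is smaller than the patch. The recorded 0-based
#' `crop_offset` maps patch voxel `(i, j, k)` (1-based R index) back to
#' source voxel `crop_offset + (i, j, k)`.
#'
#' @param vol a `multimodal_volume`.
#' @param labels the paired `label_volume`.
#' @param side patch side in voxels (default 128).
#' @return a `patch_case` with elements `image` (`[side, side, side, 4]`),
#'   `labels`, `crop_offset` (0-based), `padding` and `spacing`.
#' @export
crop_case <- function(vol, labels, side = 128L) {
  stopifnot_same_shape(vol$data[, , , 1], labels$labels, "image and labels")
  idx <- which(labels$labels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    radsurv_abort("label volume is empty; case skipped",
                  "radsurv_skip_case")
  shp <- dim(labels$labels)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  ctr <- floor((lo + hi) / 2)
  start <- ctr - floor(side / 2) + 1L          # 1-based candidate start
  start <- pmax(1L, pmin(start, shp - side + 1L))
  start <- pmax(start, 1L)                     # if shp < side, start at 1
  take <- pmin(side, shp - start + 1L)
  pad <- side - take
  img <- array(0, dim = c(side, side, side, 4))
  lab <- array(0L, dim = c(side, side, side))
  sx <- seq.int(start[1], start[1] + take[1] - 1L)
  sy <- seq.int(start[2], start[2] + take[2] - 1L)
  sz <- seq.int(start[3], start[3] + take[3] - 1L)
  img[seq_len(take[1]), seq_len(take[2]), seq_len(take[3]), ] <-
    vol$data[sx, sy, sz, , drop = FALSE]
  lab[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])] <-
    labels$labels[sx, sy, sz]
  structure(list(image = img, labels = lab,
                 crop_offset = as.integer(start - 1L),
                 padding = as.integer(pad),
                 spacing = vol$spacing),
            class = "patch_case")
}

#' Map a patch voxel index back to the source volume
#'
#' @param case a `patch_case`.
#' @param ijk integer vector or matrix of 1-based patch voxel indices.
#' @return the corresponding 1-based source voxel indices.
#' @export
uncrop_index <- function(case, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  sweep(ijk, 2, case$crop_offset, "+")
}
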