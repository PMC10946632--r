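#' Synthetic nested-ellipsoid tumor phantoms
#'
#' The phantom emulates the geometry and contrast structure of a
#' skull-stripped, co-registered multimodal glioma scan: a large "brain"
#' ellipsoid of nonzero tissue on a zero background, and three nested tumor
#' ellipsoids rendering the BraTS label convention -- enhancing tumor
#' (label 4) inside the tumor core, a necrotic core shell (label 1) between
#' ET and the TC ellipsoid, and edema (label 2) between TC and the whole
#' tumor ellipsoid. Each modality gets its own tissue intensity means
#' (T1ce bright enhancement, FLAIR/T2 bright edema, dark necrosis on T1)
#' plus additive Gaussian noise.
#'
#' @name phantom_fixtures
NULL

#' Default survival coefficients for the phantom cohort (days per unit)
#' @return named numeric vector of generative coefficients over
#'   `(intercept, wt_vol_ml, et_vol_ml, age, grade_hgg)`.
#' @export
cohort_spec_defaults <- function() {
  c(intercept = 900, wt_vol_ml = -18, et_vol_ml = -40, age = -6,
    grade_hgg = -120)
}

default_tissue_means <- function() {
  # rows: tissue; cols: t1, t1ce, t2, flair (arbitrary intensity units)
  m <- rbind(
    brain     = c(100, 100,  80,  90),
    edema     = c( 80,  85, 140, 150),
    necrotic  = c( 60,  65, 120, 110),
    enhancing = c(110, 180, 100, 120)
  )
  colnames(m) <- RADSURV_MODALITIES
  m
}

#' Specify one phantom case
#'
#' @param shape integer length-3 grid shape (default `c(64, 64, 64)`).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param center ellipsoid centre in voxel units (default grid centre).
#' @param wt_semiaxes,tc_semiaxes,et_semiaxes semi-axes (mm) of the whole
#'   tumor, tumor core and enhancing tumor ellipsoids; must be nested.
#' @param brain_semiaxes semi-axes of the brain tissue ellipsoid.
#' @param tissue_means 4x4 matrix of per-tissue, per-modality intensity
#'   means (rows brain/edema/necrotic/enhancing).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                         center = NULL,
                         wt_semiaxes = c(14, 12, 13),
                         tc_semiaxes = c(9, 8, 8),
                         et_semiaxes = c(5, 4.5, 5),
                         brain_semiaxes = NULL,
                         tissue_means = default_tissue_means(),
                         noise_sd = 5, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  if (is.null(brain_semiaxes)) brain_semiaxes <- shape * spacing / 2 - spacing
  if (any(et_semiaxes > tc_semiaxes) || any(tc_semiaxes > wt_semiaxes))
    radsurv_abort("ellipsoids must be nested (et <= tc <= wt per axis)",
                  "radsurv_error_validation")
  if (noise_sd < 0)
    radsurv_abort("noise_sd must be >= 0", "radsurv_error_validation")
  ext <- wt_semiaxes / spacing
  if (any(center - ext < 1) || any(center + ext > shape))
    radsurv_abort("whole-tumor ellipsoid exceeds the grid",
                  "radsurv_error_validation")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 center = as.numeric(center),
                 wt_semiaxes = wt_semiaxes, tc_semiaxes = tc_semiaxes,
                 et_semiaxes = et_semiaxes, brain_semiaxes = brain_semiaxes,
                 tissue_means = tissue_means, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  ax <- (seq_len(shape[1]) - center[1]) * spacing[1] / semiaxes[1]
  ay <- (seq_len(shape[2]) - center[2]) * spacing[2] / semiaxes[2]
  az <- (seq_len(shape[3]) - center[3]) * spacing[3] / semiaxes[3]
  d2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  d2 <= 1
}

#' Render one phantom case
#'
#' @param spec a `phantom_spec`.
#' @return a list with `volume` (`multimodal_volume`), `labels`
#'   (`label_volume`) and `truth` (analytic volumes in mm^3, voxel counts,
#'   geometry).
#' @export
make_phantom_case <- function(spec) {
  shp <- spec$shape
  sp <- spec$spacing
  brain <- ellipsoid_mask(shp, sp, spec$center, spec$brain_semiaxes)
  wt <- ellipsoid_mask(shp, sp, spec$center, spec$wt_semiaxes)
  tc <- ellipsoid_mask(shp, sp, spec$center, spec$tc_semiaxes)
  et <- ellipsoid_mask(shp, sp, spec$center, spec$et_semiaxes)
  lab <- array(0L, dim = shp)
  lab[wt] <- 2L   # edema
  lab[tc] <- 1L   # necrotic / non-enhancing core shell
  lab[et] <- 4L   # enhancing tumor
  set.seed(spec$seed)
  data <- array(0, dim = c(shp, 4))
  tm <- spec$tissue_means
  for (m in seq_len(4)) {
    ch <- array(0, dim = shp)
    ch[brain] <- tm["brain", m]
    ch[lab == 2L] <- tm["edema", m]
    ch[lab == 1L] <- tm["necrotic", m]
    ch[lab == 4L] <- tm["enhancing", m]
    support <- brain | wt
    noise <- rnorm(sum(support), 0, spec$noise_sd)
    ch[support] <- pmax(ch[support] + noise, 1)  # keep tissue nonzero
    data[, , , m] <- ch
  }
  vvol <- prod(sp)
  truth <- list(
    wt_volume_mm3 = 4 / 3 * pi * prod(spec$wt_semiaxes),
    tc_volume_mm3 = 4 / 3 * pi * prod(spec$tc_semiaxes),
    et_volume_mm3 = 4 / 3 * pi * prod(spec$et_semiaxes),
    wt_voxels = sum(wt), tc_voxels = sum(tc), et_voxels = sum(et),
    voxel_volume_mm3 = vvol, center = spec$center,
    wt_semiaxes = spec$wt_semiaxes, tc_semiaxes = spec$tc_semiaxes,
    et_semiaxes = spec$et_semiaxes
  )
  list(volume = multimodal_volume(data, spacing = sp),
       labels = label_volume(lab, spacing = sp),
       truth = truth)
}

#' Specify a phantom cohort with survival ground truth
#'
#' Per-case tumor geometry, age and grade are sampled, and overall survival
#' is generated as `os_days = w . features + noise`, floored at 1 day. The
#' generative features are interpretable: intercept, WT / ET volumes (mL),
#' age (years) and high-grade indicator. Defaults give a cohort with median
#' survival around 300 days and a spread of roughly 100-550 days.
#'
#' @param n number of cases.
#' @param shape,spacing grid shape and voxel size passed to each case.
#' @param wt_range range (mm) for whole-tumor semi-axes (sampled uniformly,
#'   per axis).
#' @param tc_frac,et_frac ranges for the TC/WT and ET/TC semi-axis ratios.
#' @param age_range uniform range for age in years.
#' @param hgg_prob probability a case is high-grade (`grade = "HGG"`).
#' @param w named survival coefficient vector over
#'   `(intercept, wt_vol_ml, et_vol_ml, age, grade_hgg)` in days per unit.
#' @param os_noise_sd survival noise sd in days.
#' @param noise_sd image intensity noise sd.
#' @param seed master RNG seed.
#' @return a `phantom_cohort`: list of per-case `phantom_spec`s, a
#'   `clinical` data frame (case_id, age, grade, os_days) and a `truth`
#'   record (generative feature matrix, `w`, `os_noise_sd`).
#' @export
make_cohort <- function(n, shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                        wt_range = c(9, 16), tc_frac = c(0.5, 0.75),
                        et_frac = c(0.45, 0.7), age_range = c(40, 75),
                        hgg_prob = 0.8, w = cohort_spec_defaults(),
                        os_noise_sd = 30, noise_sd = 5, seed = 1L) {
  if (n < 1) radsurv_abort("n must be >= 1", "radsurv_error_validation")
  set.seed(derive_seed(seed, 0L))
  specs <- vector("list", n)
  feats <- matrix(0, n, 5,
                  dimnames = list(NULL, c("intercept", "wt_vol_ml",
                                          "et_vol_ml", "age", "grade_hgg")))
  age <- runif(n, age_range[1], age_range[2])
  hgg <- runif(n) < hgg_prob
  for (i in seq_len(n)) {
    wt_ax <- runif(3, wt_range[1], wt_range[2])
    tc_ax <- wt_ax * runif(1, tc_frac[1], tc_frac[2])
    et_ax <- tc_ax * runif(1, et_frac[1], et_frac[2])
    ctr <- (shape + 1) / 2 + runif(3, -2, 2)
    specs[[i]] <- phantom_spec(shape = shape, spacing = spacing,
                               center = ctr, wt_semiaxes = wt_ax,
                               tc_semiaxes = tc_ax, et_semiaxes = et_ax,
                               noise_sd = noise_sd,
                               seed = derive_seed(seed, i))
    feats[i, ] <- c(1,
                    4 / 3 * pi * prod(wt_ax) / 1000,
                    4 / 3 * pi * prod(et_ax) / 1000,
                    age[i], as.numeric(hgg[i]))
  }
  os <- as.numeric(feats %*% w[colnames(feats)])
  if (os_noise_sd > 0) os <- os + rnorm(n, 0, os_noise_sd)
  os <- pmax(os, 1)
  clinical <- data.frame(
    case_id = sprintf("phantom_%03d", seq_len(n)),
    age = age, grade = ifelse(hgg, "HGG", "LGG"), os_days = os,
    stringsAsFactors = FALSE
  )
  structure(list(specs = specs, clinical = clinical,
                 truth = list(features = feats, w = w,
                              os_noise_sd = os_noise_sd, seed = seed)),
            class = "phantom_cohort")
}

#' Write a cohort to disk as NIfTI files plus a case manifest
#'
#' Produces the standard ingestion layout: per case four modality NIfTIs and
#' a segmentation NIfTI, plus `manifest.csv` with columns case_id, t1, t1ce,
#' t2, flair, seg, age, grade, os_days.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- cohort$clinical
  rows <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    case <- make_phantom_case(cohort$specs[[i]])
    id <- cl$case_id[i]
    paths <- file.path(dir, paste0(id, "_", RADSURV_MODALITIES, ".nii.gz"))
    segp <- file.path(dir, paste0(id, "_seg.nii.gz"))
    save_volumes(case$volume, paths)
    save_volumes(case$labels, segp)
    rows[[i]] <- data.frame(case_id = id, t1 = paths[1], t1ce = paths[2],
                            t2 = paths[3], flair = paths[4], seg = segp,
                            age = cl$age[i], grade = cl$grade[i],
                            os_days = cl$os_days[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
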