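test_that("discretization follows the binning rules", {
  img <- array(0:9, c(10, 1, 1))
  msk <- array(1L, c(10, 1, 1))
  roi <- discretize_roi(img, msk, feature_config(bin_width = 5))
  expect_identical(as.vector(roi$levels), rep(c(1L, 2L), each = 5))
  expect_identical(roi$Ng, 2L)
  roi2 <- discretize_roi(img, msk, feature_config(fixed_bin_count = 4))
  expect_identical(roi2$Ng, 4L)
  expect_identical(max(roi2$levels), 4L)     # max intensity maps to Ng
  expect_identical(as.vector(table(roi2$levels[msk == 1])),
                   c(3L, 2L, 2L, 3L))
  cst <- discretize_roi(array(7, c(3, 3, 3)), array(1L, c(3, 3, 3)),
                        feature_config(fixed_bin_count = 4))
  expect_identical(cst$Ng, 1L)
  expect_error(discretize_roi(img, msk * 0L), class = "radsurv_error_validation")
})

test_that("GLCM features match hand-built matrices and degenerate rules", {
  # constant ROI: a single co-occurrence cell
  cst <- discretize_roi(array(7, c(3, 3, 3)), array(1L, c(3, 3, 3)),
                        feature_config(fixed_bin_count = 4))
  f <- glcm_features(cst)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["JointEntropy"]), 0)
  expect_true(is.na(f["Correlation"]))
  # 1-D stripe 1,2,1,2: all co-occurrences between adjacent levels
  stripe <- array(rep(c(0, 10), 4), c(8, 1, 1))
  roi <- discretize_roi(stripe, array(1L, c(8, 1, 1)),
                        feature_config(fixed_bin_count = 2))
  f2 <- glcm_features(roi)  # only the x offset yields pairs
  expect_equal(unname(f2["Contrast"]), 1)
})

test_that("all GLCM features equal the brute-force oracle on a random ROI", {
  rr <- random_roi(side = 8L, ng = 6L, seed = 21L)
  got <- glcm_features(rr$roi, rr$cfg)
  per_dir <- list()
  for (d in seq_len(nrow(oracle_offsets()))) {
    P <- oracle_glcm_matrix(rr$roi$levels, rr$roi$Ng, oracle_offsets()[d, ])
    if (sum(P) > 0)
      per_dir[[length(per_dir) + 1]] <- oracle_glcm_features(P)
  }
  want <- colMeans(do.call(rbind, per_dir))
  expect_equal(got[names(want)], want, tolerance = 1e-8)
})

test_that("GLRLM features follow run structure and the enumeration oracle", {
  # every voxel a distinct level: all runs have length 1
  img <- array(seq_len(8), c(2, 2, 2))
  roi <- discretize_roi(img, array(1L, c(2, 2, 2)),
                        feature_config(fixed_bin_count = 8))
  f <- glrlm_features(roi)
  expect_equal(unname(f["ShortRunEmphasis"]), 1)
  expect_equal(unname(f["RunPercentage"]), 1)
  # a line of n identical voxels: single run along the line
  n <- 6
  line <- array(5, c(n, 1, 1))
  roil <- discretize_roi(line, array(1L, c(n, 1, 1)),
                         feature_config(fixed_bin_count = 1))
  P <- radsurv:::rx_run_counts(roil$levels, dim(roil$levels), roil$Ng,
                               c(1L, 0L, 0L), n)
  lre <- sum(P * matrix((1:n)^2, 1, n, byrow = TRUE)) / sum(P)
  expect_equal(lre, n^2)
  # oracle equivalence on a random ROI
  rr <- random_roi(side = 8L, ng = 5L, seed = 22L)
  got <- glrlm_features(rr$roi, rr$cfg)
  np <- sum(rr$roi$mask)
  maxlen <- max(dim(rr$roi$levels))
  per_dir <- t(vapply(seq_len(nrow(oracle_offsets())), function(d) {
    P <- oracle_run_matrix(rr$roi$levels, rr$roi$Ng, oracle_offsets()[d, ],
                           maxlen)
    oracle_szm_features(P, np)
  }, numeric(16)))
  want <- colMeans(per_dir)
  map <- c(GrayLevelNonUniformity = "GrayLevelNonUniformity",
           HighGrayLevelRunEmphasis = "HighGrayLevelZoneEmphasis",
           LongRunEmphasis = "LargeAreaEmphasis",
           LongRunLowGrayLevelEmphasis = "LargeAreaLowGrayLevelEmphasis",
           LowGrayLevelRunEmphasis = "LowGrayLevelZoneEmphasis",
           RunEntropy = "ZoneEntropy",
           RunLengthNonUniformity = "SizeZoneNonUniformity",
           RunLengthNonUniformityNormalized = "SizeZoneNonUniformityNormalized",
           GrayLevelVariance = "GrayLevelVariance",
           RunPercentage = "ZonePercentage",
           LongRunHighGrayLevelEmphasis = "LargeAreaHighGrayLevelEmphasis",
           RunVariance = "ZoneVariance",
           ShortRunEmphasis = "SmallAreaEmphasis",
           ShortRunHighGrayLevelEmphasis = "SmallAreaHighGrayLevelEmphasis",
           GrayLevelNonUniformityNormalized = "GrayLevelNonUniformityNormalized",
           ShortRunLowGrayLevelEmphasis = "SmallAreaLowGrayLevelEmphasis")
  expect_equal(unname(got[names(map)]), unname(want[map]),
               tolerance = 1e-8)
})

test_that("GLSZM features follow zone structure and the flood-fill oracle", {
  # uniform ROI: one zone covering all Nv voxels
  cst <- discretize_roi(array(7, c(3, 3, 3)), array(1L, c(3, 3, 3)),
                        feature_config(fixed_bin_count = 4))
  f <- glszm_features(cst)
  expect_equal(unname(f["ZonePercentage"]), 1 / 27)
  # two separated single-voxel zones of different levels
  img <- array(0, c(5, 5, 5))
  msk <- array(0L, c(5, 5, 5))
  img[1, 1, 1] <- 0; img[5, 5, 5] <- 10
  msk[1, 1, 1] <- 1L; msk[5, 5, 5] <- 1L
  roi2 <- discretize_roi(img, msk, feature_config(fixed_bin_count = 2))
  f2 <- glszm_features(roi2)
  expect_equal(unname(f2["SmallAreaEmphasis"]), 1)
  # oracle equivalence
  rr <- random_roi(side = 8L, ng = 4L, seed = 23L)
  got <- glszm_features(rr$roi, rr$cfg)
  zs <- radsurv:::rx_zone_sizes(rr$roi$levels, dim(rr$roi$levels))
  want <- oracle_szm_features(
    oracle_zone_matrix(rr$roi$levels, rr$roi$Ng, max(zs[, 2])),
    sum(rr$roi$mask))
  expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-8)
})

test_that("GLDM features follow dependence structure and the scan oracle", {
  # single-voxel ROI: one entry at dependence size 1
  img <- array(1, c(3, 3, 3))
  msk <- array(0L, c(3, 3, 3)); msk[2, 2, 2] <- 1L
  roi <- discretize_roi(img, msk, feature_config(fixed_bin_count = 1))
  f <- gldm_features(roi)
  expect_equal(unname(f["SmallDependenceEmphasis"]), 1)
  expect_equal(unname(f["LargeDependenceEmphasis"]), 1)
  # constant 3x3x3 cube, alpha 0: centre voxel has dependence 26 + 1
  cst <- discretize_roi(array(7, c(3, 3, 3)), array(1L, c(3, 3, 3)),
                        feature_config(fixed_bin_count = 1))
  P <- radsurv:::rx_dependence_counts(cst$levels, dim(cst$levels), 1L, 0L)
  expect_equal(P[1, 27], 1)                 # the centre voxel
  # oracle equivalence (map shared engine names onto the GLDM row)
  rr <- random_roi(side = 8L, ng = 4L, seed = 24L)
  got <- gldm_features(rr$roi, rr$cfg)
  wantP <- oracle_dependence_matrix(rr$roi$levels, rr$roi$Ng,
                                    rr$cfg$gldm_alpha)
  want <- oracle_szm_features(wantP, sum(rr$roi$mask))
  map <- c(DependenceEntropy = "ZoneEntropy",
           DependenceVariance = "ZoneVariance",
           GrayLevelNonUniformity = "GrayLevelNonUniformity",
           HighGrayLevelEmphasis = "HighGrayLevelZoneEmphasis",
           LargeDependenceHighGrayLevelEmphasis = "LargeAreaHighGrayLevelEmphasis",
           LowGrayLevelEmphasis = "LowGrayLevelZoneEmphasis",
           LargeDependenceLowGrayLevelEmphasis = "LargeAreaLowGrayLevelEmphasis",
           SmallDependenceHighGrayLevelEmphasis = "SmallAreaHighGrayLevelEmphasis",
           SmallDependenceEmphasis = "SmallAreaEmphasis",
           GrayLevelVariance = "GrayLevelVariance",
           DependenceNonUniformity = "SizeZoneNonUniformity",
           SmallDependenceLowGrayLevelEmphasis = "SmallAreaLowGrayLevelEmphasis",
           LargeDependenceEmphasis = "LargeAreaEmphasis",
           DependenceNonUniformityNormalized = "SizeZoneNonUniformityNormalized")
  expect_equal(unname(got[names(map)]), unname(want[map]),
               tolerance = 1e-8)
})

test_that("first-order statistics match hand values and the sort oracle", {
  img <- array(c(1, 2, 3, 4), c(4, 1, 1))
  msk <- array(1L, c(4, 1, 1))
  f <- first_order_features(img, msk)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Energy"]), 30)
  cst <- first_order_features(array(5, c(3, 3, 3)), array(1L, c(3, 3, 3)))
  expect_equal(unname(cst["Variance"]), 0)
  expect_equal(unname(cst["Uniformity"]), 1)
  expect_equal(unname(cst["Entropy"]), 0)
  set.seed(31)
  v <- rnorm(100)
  img2 <- array(v, c(100, 1, 1))
  f2 <- first_order_features(img2, array(1L, c(100, 1, 1)))
  expect_equal(unname(f2["10Percentile"]), oracle_percentile(v, 0.10))
  expect_equal(unname(f2["90Percentile"]), oracle_percentile(v, 0.90))
  expect_equal(unname(f2["InterquartileRange"]),
               oracle_percentile(v, 0.75) - oracle_percentile(v, 0.25))
})

test_that("shape features are close to analytic values for a digital ball", {
  ball <- digital_ball(10L)
  sf <- shape_features(ball)
  expect_gte(unname(sf["Sphericity"]), 0.95)
  expect_lte(unname(sf["Sphericity"]), 1.0)
  expect_lt(abs(sf["MeshVolume"] - 4188.79) / 4188.79, 0.05)
  expect_lt(abs(sf["Elongation"] - 1), 0.02)
  expect_lt(abs(sf["Flatness"] - 1), 0.02)
  expect_equal(unname(sf["Maximum3DDiameter"]), 20, tolerance = 0.1)
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  s1 <- shape_features(single)
  expect_equal(unname(s1["VoxelVolume"]), 1)
  expect_gt(unname(s1["MeshVolume"]), 0)
  plane <- array(0L, c(9, 9, 9)); plane[3:7, 3:7, 5] <- 1L
  expect_equal(unname(shape_features(plane)["Flatness"]), 0)
})

test_that("interpolated statistics report geometry exactly", {
  img <- array(seq_len(27), c(3, 3, 3))
  msk <- array(1L, c(3, 3, 3))
  iv <- interpolated_statistics(img, msk, spacing = c(1, 2, 3))
  expect_equal(unname(iv["VoxelNum"]), 27)
  expect_equal(unname(iv["VolumeNum"]), 1)
  expect_equal(unname(iv[c("CenterOfMassIndex_x", "CenterOfMassIndex_y",
                           "CenterOfMassIndex_z")]), c(2, 2, 2))
  expect_equal(unname(iv["Mean"]), 14)
  expect_equal(unname(iv[c("Spacing_x", "Spacing_y", "Spacing_z")]),
               c(1, 2, 3))
  expect_equal(unname(iv[c("BoundingBox_dx", "BoundingBox_dy",
                           "BoundingBox_dz")]), c(3, 3, 3))
})

test_that("wavelet decomposition is orthogonal and complete", {
  set.seed(41)
  img <- array(rnorm(16 * 12 * 8), c(16, 12, 8))
  bands <- wavelet_bands(img)
  expect_length(bands, 8)
  expect_identical(names(bands)[1], "LLL")
  expect_identical(dim(bands$HHH), c(8L, 6L, 4L))
  rec <- wavelet_reconstruct(bands)
  expect_lt(max(abs(rec - img)), 1e-6)
  # constant image: detail bands vanish (vanishing moments)
  cst <- array(3, c(8, 8, 8))
  bc <- wavelet_bands(cst)
  e_lll <- sum(bc$LLL^2)
  for (nm in setdiff(names(bc), "LLL"))
    expect_lt(sum(bc[[nm]]^2), 1e-10 * e_lll)
  expect_error(wavelet_bands(array(0, c(4, 8, 8))),
               class = "radsurv_error_validation")
})

test_that("texture features are invariant where theory says they must be", {
  rr <- random_roi(side = 8L, ng = 5L, seed = 51L)
  # adding a constant with fixed-bin-count discretization changes nothing
  roi_shift <- discretize_roi(rr$img + 123.4, rr$mask, rr$cfg)
  expect_identical(roi_shift$levels, rr$roi$levels)
  # 90-degree rotation about z permutes directions; mean-aggregated
  # features are unchanged
  rot <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  img_r <- array(rot(rr$img), dim(rr$img))
  msk_r <- array(rot(rr$mask), dim(rr$mask))
  roi_r <- discretize_roi(img_r, msk_r, rr$cfg)
  for (fn in list(glcm_features, glrlm_features)) {
    a <- fn(rr$roi, rr$cfg)
    b <- fn(roi_r, rr$cfg)
    expect_equal(a[!is.na(a)], b[!is.na(a)], tolerance = 1e-8)
  }
  expect_equal(glszm_features(rr$roi, rr$cfg),
               glszm_features(roi_r, rr$cfg), tolerance = 1e-8)
  expect_equal(gldm_features(rr$roi, rr$cfg),
               gldm_features(roi_r, rr$cfg), tolerance = 1e-8)
})

test_that("case-level extraction is deterministic with the documented size", {
  pc <- std_patch()
  reg <- encode_regions(pc$labels)
  cfg <- feature_config(fixed_bin_count = 16)
  v1 <- extract_case_features(pc$image, reg, cfg, spacing = pc$spacing)
  expect_length(v1, feature_count())
  v2 <- extract_case_features(pc$image, reg, cfg, spacing = pc$spacing)
  expect_identical(v1, v2)
  expect_false(anyDuplicated(names(v1)) > 0)
  # empty region yields NA blocks, not zeros
  reg0 <- reg
  reg0$et <- reg$et * 0L
  v3 <- extract_case_features(pc$image, reg0, cfg, spacing = pc$spacing)
  et_cols <- grepl("_et_", names(v3))
  expect_true(all(is.na(v3[et_cols])))
  expect_false(anyNA(v3[!et_cols]))
})

test_that("the registry mirrors the published category cardinalities", {
  reg <- feature_registry()
  counts <- table(reg$category)
  expect_equal(unname(counts[c("glcm", "firstorder", "glrlm", "glszm",
                               "gldm", "shape", "interpstat")]),
               c(22L, 18L, 16L, 16L, 14L, 14L, 9L), ignore_attr = TRUE)
  expect_false(any(duplicated(paste(reg$category, reg$name))))
})
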