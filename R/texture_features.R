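#' Gray-level texture-matrix features
#'
#' Four families of texture features computed from a discretized region of
#' interest: co-occurrence (GLCM, 22 features), run length (GLRLM, 16),
#' size zone (GLSZM, 16) and dependence (GLDM, 14). GLCM and GLRLM are
#' built per direction over the 13 unique 3-D offsets and aggregated by the
#' mean of the per-direction feature values; GLSZM (26-connected zones) and
#' GLDM (26-neighbourhood dependence counts) are direction-free. Feature
#' definitions follow the common radiomics conventions for these matrices.
#' Features that are undefined on a degenerate ROI (e.g. correlation on a
#' single gray level) are returned as `NA`.
#'
#' @name radiomic_features
NULL

glcm_feature_names <- function() c(
  "Autocorrelation", "InverseVariance", "ClusterShade", "Correlation",
  "DifferenceAverage", "SumEntropy", "JointEnergy", "ClusterTendency",
  "Contrast", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
  "MaximumProbability", "DifferenceVariance", "DifferenceEntropy",
  "SumSquares", "JointAverage", "ClusterProminence")

glrlm_feature_names <- function() c(
  "GrayLevelNonUniformity", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis", "RunEntropy",
  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
  "GrayLevelVariance", "RunPercentage", "LongRunHighGrayLevelEmphasis",
  "RunVariance", "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "GrayLevelNonUniformityNormalized", "ShortRunLowGrayLevelEmphasis")

glszm_feature_names <- function() c(
  "GrayLevelNonUniformity", "HighGrayLevelZoneEmphasis",
  "LargeAreaEmphasis", "GrayLevelVariance",
  "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
  "SizeZoneNonUniformity", "GrayLevelNonUniformityNormalized",
  "SizeZoneNonUniformityNormalized", "SmallAreaHighGrayLevelEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
  "ZoneVariance")

gldm_feature_names <- function() c(
  "DependenceEntropy", "DependenceVariance", "GrayLevelNonUniformity",
  "HighGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LowGrayLevelEmphasis", "LargeDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis", "SmallDependenceEmphasis",
  "GrayLevelVariance", "DependenceNonUniformity",
  "SmallDependenceLowGrayLevelEmphasis", "LargeDependenceEmphasis",
  "DependenceNonUniformityNormalized")

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

glcm_features_from_matrix <- function(P) {
  # P: symmetric co-occurrence count matrix (Ng x Ng)
  ng <- nrow(P)
  tot <- sum(P)
  p <- P / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(px * seq_len(ng))           # symmetric: mux = muy
  sig2 <- sum(px * (seq_len(ng) - mu)^2)
  # diagonal-band marginals
  kd <- 0:(ng - 1)
  pxmy <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  pxpy <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  da <- sum(kd * pxmy)
  hx <- entropy2(px)
  hxy <- entropy2(p)
  pxy_prod <- outer(px, px)
  nz <- p > 0 & pxy_prod > 0
  hxy1 <- -sum(p[nz] * log2(pxy_prod[nz]))
  nz2 <- pxy_prod > 0
  hxy2 <- -sum(pxy_prod[nz2] * log2(pxy_prod[nz2]))
  corr <- if (sig2 > 0) (sum(p * i * j) - mu^2) / sig2 else NA_real_
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- abs(i - j) > 0
  c(
    Autocorrelation = sum(p * i * j),
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    ClusterShade = sum(p * (i + j - 2 * mu)^3),
    Correlation = corr,
    DifferenceAverage = da,
    SumEntropy = entropy2(pxpy),
    JointEnergy = sum(p^2),
    ClusterTendency = sum(p * (i + j - 2 * mu)^2),
    Contrast = sum(p * (i - j)^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    MaximumProbability = max(p),
    DifferenceVariance = sum(pxmy * (kd - da)^2),
    DifferenceEntropy = entropy2(pxmy),
    SumSquares = sum(p * (i - mu)^2),
    JointAverage = mu,
    ClusterProminence = sum(p * (i + j - 2 * mu)^4)
  )
}

#' GLCM features (22) of a discretized ROI
#'
#' Symmetric co-occurrence matrices at the configured distance over the 13
#' directions, each normalized to probabilities; the 22 features are
#' computed per direction and aggregated by their mean.
#'
#' @param roi a `discretized_roi`.
#' @param cfg a [feature_config()].
#' @return named numeric vector of 22 features.
#' @export
glcm_features <- function(roi, cfg = feature_config()) {
  dirs <- texture_directions() * cfg$glcm_distance
  counts <- rx_pair_counts(roi$levels, dim(roi$levels), roi$Ng, dirs)
  per_dir <- list()
  for (d in seq_len(nrow(dirs))) {
    C <- matrix(counts[, , d], roi$Ng, roi$Ng)
    P <- C + t(C)                        # symmetric mode
    if (sum(P) == 0) next                # no pairs along this direction
    per_dir[[length(per_dir) + 1]] <- glcm_features_from_matrix(P)
  }
  if (!length(per_dir))
    return(setNames(rep(NA_real_, 22), glcm_feature_names()))
  agg <- colMeans(do.call(rbind, per_dir))
  agg[glcm_feature_names()]
}

rlm_style_features <- function(P, np, kind) {
  # shared feature engine for GLRLM (runs), GLSZM (zones), GLDM
  # (dependencies): P counts over (gray level i, size j), np in-mask voxels
  ng <- nrow(P)
  iv <- matrix(seq_len(ng), ng, ncol(P))
  jv <- t(matrix(seq_len(ncol(P)), ncol(P), ng))
  n <- sum(P)
  p <- P / n
  pg <- rowSums(P)
  pr <- colSums(P)
  mu_i <- sum(p * iv)
  mu_j <- sum(p * jv)
  base <- c(
    GrayLevelNonUniformity = sum(pg^2) / n,
    GrayLevelNonUniformityNormalized = sum(pg^2) / n^2,
    SizeNonUniformity = sum(pr^2) / n,
    SizeNonUniformityNormalized = sum(pr^2) / n^2,
    GrayLevelVariance = sum(p * (iv - mu_i)^2),
    SizeVariance = sum(p * (jv - mu_j)^2),
    Entropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / iv^2) / n,
    HighGrayLevelEmphasis = sum(P * iv^2) / n,
    SmallEmphasis = sum(P / jv^2) / n,
    LargeEmphasis = sum(P * jv^2) / n,
    SmallLowGray = sum(P / (iv^2 * jv^2)) / n,
    SmallHighGray = sum(P * iv^2 / jv^2) / n,
    LargeLowGray = sum(P * jv^2 / iv^2) / n,
    LargeHighGray = sum(P * iv^2 * jv^2) / n,
    Percentage = n / np
  )
  if (kind == "glrlm") {
    setNames(base[c("GrayLevelNonUniformity", "HighGrayLevelEmphasis",
                    "LargeEmphasis", "LargeLowGray", "LowGrayLevelEmphasis",
                    "Entropy", "SizeNonUniformity",
                    "SizeNonUniformityNormalized", "GrayLevelVariance",
                    "Percentage", "LargeHighGray", "SizeVariance",
                    "SmallEmphasis", "SmallHighGray",
                    "GrayLevelNonUniformityNormalized", "SmallLowGray")],
             glrlm_feature_names())
  } else if (kind == "glszm") {
    setNames(base[c("GrayLevelNonUniformity", "HighGrayLevelEmphasis",
                    "LargeEmphasis", "GrayLevelVariance", "LargeLowGray",
                    "LowGrayLevelEmphasis", "SizeNonUniformity",
                    "GrayLevelNonUniformityNormalized",
                    "SizeNonUniformityNormalized", "SmallHighGray",
                    "SmallLowGray", "SmallEmphasis", "LargeHighGray",
                    "Entropy", "Percentage", "SizeVariance")],
             glszm_feature_names())
  } else {
    setNames(base[c("Entropy", "SizeVariance", "GrayLevelNonUniformity",
                    "HighGrayLevelEmphasis", "LargeHighGray",
                    "LowGrayLevelEmphasis", "LargeLowGray", "SmallHighGray",
                    "SmallEmphasis", "GrayLevelVariance",
                    "SizeNonUniformity", "SmallLowGray", "LargeEmphasis",
                    "SizeNonUniformityNormalized")],
             gldm_feature_names())
  }
}

#' GLRLM features (16) of a discretized ROI
#'
#' Runs are maximal collinear segments of equal gray level within the mask;
#' matrices are built per direction (13 offsets) and features aggregated by
#' their mean.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(roi, cfg = feature_config()) {
  dirs <- texture_directions()
  np <- sum(roi$mask)
  maxlen <- max(dim(roi$levels))
  per_dir <- lapply(seq_len(nrow(dirs)), function(d) {
    P <- rx_run_counts(roi$levels, dim(roi$levels), roi$Ng, dirs[d, ],
                       maxlen)
    rlm_style_features(P, np, "glrlm")
  })
  colMeans(do.call(rbind, per_dir))
}

#' GLSZM features (16) of a discretized ROI
#'
#' Zones are 26-connected components of equal gray level; a single
#' direction-free matrix over (level, zone size).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(roi, cfg = feature_config()) {
  zs <- rx_zone_sizes(roi$levels, dim(roi$levels))
  np <- sum(roi$mask)
  maxsz <- max(zs[, 2])
  P <- matrix(0, roi$Ng, maxsz)
  for (k in seq_len(nrow(zs))) P[zs[k, 1], zs[k, 2]] <- P[zs[k, 1], zs[k, 2]] + 1
  rlm_style_features(P, np, "glszm")
}

#' GLDM features (14) of a discretized ROI
#'
#' The dependence size of a voxel is one plus the number of in-mask
#' 26-neighbours whose absolute level difference is at most `gldm_alpha`;
#' the matrix counts voxels over (level, dependence size).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(roi, cfg = feature_config()) {
  Pn <- rx_dependence_counts(roi$levels, dim(roi$levels), roi$Ng,
                             cfg$gldm_alpha)
  # column j of Pn = (dependent neighbours = j - 1); dependence size = j
  np <- sum(roi$mask)
  rlm_style_features(Pn, np, "gldm")
}
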