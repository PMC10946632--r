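#' First-order intensity statistics (18) of a region of interest
#'
#' Statistics are computed on the raw in-mask intensities; Entropy and
#' Uniformity use the discretized histogram implied by `cfg`. Percentiles
#' use linear interpolation between order statistics. Skewness and kurtosis
#' are the population moment ratios (kurtosis is not excess-corrected);
#' variance is the population variance.
#'
#' @param image numeric 3-D array.
#' @param mask binary array of the same shape (nonempty).
#' @param cfg a [feature_config()] controlling the histogram
#'   discretization.
#' @param spacing voxel size in mm (for Total Energy).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(image, mask, cfg = feature_config(),
                                 spacing = c(1, 1, 1)) {
  msk <- mask != 0
  if (!any(msk))
    radsurv_abort("mask is empty", "radsurv_error_validation")
  v <- image[msk]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  roi <- discretize_roi(image, mask, cfg)
  ph <- tabulate(roi$levels[msk], nbins = roi$Ng) / n
  q <- percentile_linear(v, c(0.10, 0.25, 0.75, 0.90))
  sel <- v >= q[1] & v <= q[4]
  rmad <- if (any(sel)) mean(abs(v[sel] - mean(v[sel]))) else NA_real_
  vv <- prod(spacing)
  c(
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Mean = mu,
    Median = as.numeric(stats::median(v)),
    Energy = sum(v^2),
    Entropy = entropy2(ph),
    InterquartileRange = q[3] - q[2],
    TotalEnergy = vv * sum(v^2),
    Uniformity = sum(ph^2),
    Kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    Maximum = max(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    Minimum = min(v),
    Range = max(v) - min(v),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    Variance = m2
  )
}

first_order_feature_names <- function() names(first_order_features(
  array(c(1, 2), c(2, 1, 1)), array(1, c(2, 1, 1))))
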