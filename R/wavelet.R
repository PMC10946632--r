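#' Single-level 3-D discrete wavelet decomposition
#'
#' A separable periodized orthogonal filter bank (8-tap Daubechies-4) is
#' applied along each axis, yielding the eight sub-band images LLL ... HHH
#' (L = lowpass, H = highpass, letter order = axis order). With periodic
#' extension and even, sufficiently large extents the analysis operator is
#' orthogonal, so the inverse transform (the transpose) reconstructs the
#' input exactly; each sub-band has half the extent of the input per axis,
#' and downstream feature extraction treats sub-band voxels as having twice
#' the source spacing.
#'
#' @param image numeric 3-D array; every extent must be even and at least
#'   the filter length (8).
#' @return named list of 8 sub-band arrays (`LLL`, `LLH`, ..., `HHH`).
#' @export
wavelet_bands <- function(image) {
  d <- dim(image)
  if (length(d) != 3)
    radsurv_abort("image must be a 3-D array", "radsurv_error_validation")
  if (any(d < length(db4_filter())) || any(d %% 2 != 0))
    radsurv_abort(
      "image extents must be even and at least the filter length (8)",
      "radsurv_error_validation")
  fb <- lapply(1:3, function(ax) dwt_operators(d[ax]))
  combos <- expand.grid(a1 = c("L", "H"), a2 = c("L", "H"),
                        a3 = c("L", "H"), stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    b <- image
    for (ax in 1:3) {
      M <- if (combos[r, ax] == "L") fb[[ax]]$H else fb[[ax]]$G
      b <- apply_axis(b, M, ax)
    }
    out[[paste0(combos[r, 1], combos[r, 2], combos[r, 3])]] <- b
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Inverse of [wavelet_bands()]
#'
#' @param bands named list of 8 sub-band arrays as produced by
#'   [wavelet_bands()].
#' @return the reconstructed 3-D array.
#' @export
wavelet_reconstruct <- function(bands) {
  d2 <- dim(bands$LLL)
  d <- d2 * 2L
  fb <- lapply(1:3, function(ax) dwt_operators(d[ax]))
  out <- array(0, d)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    ltr <- strsplit(nm, "")[[1]]
    for (ax in 3:1) {
      M <- if (ltr[ax] == "L") fb[[ax]]$H else fb[[ax]]$G
      b <- apply_axis(b, t(M), ax)
    }
    out <- out + b
  }
  out
}

db4_filter <- function() {
  # Daubechies-4 scaling (lowpass) filter, 8 taps, sums to sqrt(2)
  c(0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
    -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
    0.032883011666982945, -0.010597401784997278)
}

dwt_operators <- function(n) {
  # periodized analysis operators: H (n/2 x n) lowpass, G highpass
  h <- db4_filter()
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  m <- n %/% 2L
  H <- matrix(0, m, n)
  G <- matrix(0, m, n)
  for (k in seq_len(m)) {
    pos <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (t in seq_len(L)) {
      H[k, pos[t]] <- H[k, pos[t]] + h[t]
      G[k, pos[t]] <- G[k, pos[t]] + g[t]
    }
  }
  list(H = H, G = G)
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  y <- M %*% matrix(a, d[axis])
  yd <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(array(y, yd), order(perm))
}
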