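# Shared phantom fixtures, built once per test session.

std_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec(shape = c(48L, 48L, 48L), seed = 101L)
      cache <<- make_phantom_case(sp)
    }
    cache
  }
})

std_patch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      case <- std_phantom()
      vol <- zscore_normalize(case$volume)
      cache <<- crop_case(vol, case$labels, side = 32L)
    }
    cache
  }
})

random_roi <- function(side = 8L, ng = 6L, seed = 1L, mask_frac = 0.85) {
  set.seed(seed)
  img <- array(runif(side^3, 0, 100), rep(side, 3))
  mask <- array(runif(side^3) < mask_frac, rep(side, 3)) * 1L
  if (!any(mask == 1L)) mask[1] <- 1L
  cfg <- feature_config(fixed_bin_count = ng)
  list(img = img, mask = mask, cfg = cfg,
       roi = discretize_roi(img, mask, cfg))
}

digital_ball <- function(radius = 10L, pad = 3L) {
  d <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  ball <- array(0L, c(d, d, d))
  for (z in seq_len(d)) for (y in seq_len(d))
    ball[, y, z] <- as.integer((seq_len(d) - ctr)^2 + (y - ctr)^2 +
                                 (z - ctr)^2 <= radius^2)
  ball
}

# two standardized features with exact sample correlation r = 0.6
corr_fixture <- function(n = 40, r = 0.6) {
  x <- scale(seq_len(n))[, 1]
  x <- x / sqrt(sum(x^2) / (n - 1))
  e <- scale(sin(seq_len(n)))[, 1]
  e <- e - x * sum(e * x) / sum(x^2)           # orthogonalize
  e <- e / sqrt(sum(e^2) / (n - 1))
  y <- r * x + sqrt(1 - r^2) * e
  m <- cbind(f1 = x, f2 = y)
  m
}

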