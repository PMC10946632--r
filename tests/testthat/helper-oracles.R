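# Independent brute-force oracles, deliberately written with plain-R
# enumeration (loops, rle, outer) so they share no code path with the
# package implementations they check.

oracle_offsets <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

oracle_glcm_matrix <- function(lev, ng, off) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
      next
    lj <- lev[x2, y2, z2]
    if (lj == 0) next
    P[li, lj] <- P[li, lj] + 1
    P[lj, li] <- P[lj, li] + 1          # symmetric accumulation
  }
  P
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  f <- list()
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  s2 <- 0
  for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * p[i, j]
  acc <- con <- je <- jent <- idm <- id <- idmn <- idn <- 0
  cs <- ct <- cp <- mp <- ss <- iv <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    acc <- acc + v * i * j
    con <- con + v * (i - j)^2
    je <- je + v^2
    if (v > 0) jent <- jent - v * log2(v)
    idm <- idm + v / (1 + (i - j)^2)
    id <- id + v / (1 + abs(i - j))
    idmn <- idmn + v / (1 + ((i - j) / ng)^2)
    idn <- idn + v / (1 + abs(i - j) / ng)
    cs <- cs + v * (i + j - 2 * mu)^3
    ct <- ct + v * (i + j - 2 * mu)^2
    cp <- cp + v * (i + j - 2 * mu)^4
    ss <- ss + v * (i - mu)^2
    if (i != j) iv <- iv + v / (i - j)^2
    mp <- max(mp, v)
  }
  pxm <- sapply(0:(ng - 1), function(k) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (abs(i - j) == k) s <- s + p[i, j]
    s
  })
  pxp <- sapply(2:(2 * ng), function(k) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (i + j == k) s <- s + p[i, j]
    s
  })
  da <- sum((0:(ng - 1)) * pxm)
  dvar <- sum(((0:(ng - 1)) - da)^2 * pxm)
  dent <- -sum(pxm[pxm > 0] * log2(pxm[pxm > 0]))
  sent <- -sum(pxp[pxp > 0] * log2(pxp[pxp > 0]))
  px <- rowSums(p)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy1 <- 0
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  corr <- if (s2 > 0) (acc - mu^2) / s2 else NA_real_
  c(Autocorrelation = acc, InverseVariance = iv, ClusterShade = cs,
    Correlation = corr, DifferenceAverage = da, SumEntropy = sent,
    JointEnergy = je, ClusterTendency = ct, Contrast = con,
    JointEntropy = jent,
    Imc1 = if (hx > 0) (jent - hxy1) / hx else NA_real_,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - jent)))),
    Idm = idm, Idmn = idmn, Id = id, Idn = idn,
    MaximumProbability = mp, DifferenceVariance = dvar,
    DifferenceEntropy = dent, SumSquares = ss, JointAverage = mu,
    ClusterProminence = cp)
}

# all maximal runs along one offset, via rle over explicitly walked lines
oracle_run_matrix <- function(lev, ng, off, maxlen) {
  d <- dim(lev)
  P <- matrix(0, ng, maxlen)
  inside <- function(v) all(v >= 1) && all(v <= d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    v <- c(x, y, z)
    if (inside(v - off)) next           # not a line start
    vals <- integer(0)
    while (inside(v)) {
      vals <- c(vals, lev[v[1], v[2], v[3]])
      v <- v + off
    }
    r <- rle(vals)
    for (k in seq_along(r$lengths))
      if (r$values[k] > 0)
        P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1
  }
  P
}

# zone sizes via igraph connected components over same-level 26-neighbours
oracle_zone_matrix <- function(lev, ng, maxsz) {
  d <- dim(lev)
  idx <- which(lev > 0, arr.ind = TRUE)
  n <- nrow(idx)
  key <- function(v) paste(v, collapse = ",")
  id_of <- setNames(seq_len(n), apply(idx, 1, key))
  edges <- integer(0)
  for (k in seq_len(n)) {
    v <- idx[k, ]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      u <- v + c(dx, dy, dz)
      if (any(u < 1) || any(u > d)) next
      if (lev[u[1], u[2], u[3]] != lev[v[1], v[2], v[3]]) next
      j <- id_of[[key(u)]]
      if (!is.null(j) && j > k) edges <- c(edges, k, j)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)
  P <- matrix(0, ng, maxsz)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    lv <- lev[idx[members[1], 1], idx[members[1], 2], idx[members[1], 3]]
    P[lv, length(members)] <- P[lv, length(members)] + 1
  }
  P
}

oracle_dependence_matrix <- function(lev, ng, alpha) {
  d <- dim(lev)
  P <- matrix(0, ng, 27)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      u <- c(x + dx, y + dy, z + dz)
      if (any(u < 1) || any(u > d)) next
      lj <- lev[u[1], u[2], u[3]]
      if (lj > 0 && abs(lj - li) <= alpha) dep <- dep + 1
    }
    P[li, dep + 1] <- P[li, dep + 1] + 1
  }
  P
}

# size-zone style features written directly from their definitions
oracle_szm_features <- function(P, np) {
  n <- sum(P)
  ng <- nrow(P)
  nj <- ncol(P)
  p <- P / n
  f <- c(GrayLevelNonUniformity = sum(rowSums(P)^2) / n,
         HighGrayLevelZoneEmphasis = 0, LargeAreaEmphasis = 0,
         GrayLevelVariance = 0, LargeAreaLowGrayLevelEmphasis = 0,
         LowGrayLevelZoneEmphasis = 0,
         SizeZoneNonUniformity = sum(colSums(P)^2) / n,
         GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / n^2,
         SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / n^2,
         SmallAreaHighGrayLevelEmphasis = 0,
         SmallAreaLowGrayLevelEmphasis = 0, SmallAreaEmphasis = 0,
         LargeAreaHighGrayLevelEmphasis = 0, ZoneEntropy = 0,
         ZonePercentage = n / np, ZoneVariance = 0)
  mu_i <- 0
  mu_j <- 0
  for (i in 1:ng) for (j in 1:nj) {
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  for (i in 1:ng) for (j in 1:nj) {
    c0 <- P[i, j]
    if (c0 == 0) next
    f["HighGrayLevelZoneEmphasis"] <- f["HighGrayLevelZoneEmphasis"] + c0 * i^2 / n
    f["LargeAreaEmphasis"] <- f["LargeAreaEmphasis"] + c0 * j^2 / n
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] + p[i, j] * (i - mu_i)^2
    f["LargeAreaLowGrayLevelEmphasis"] <-
      f["LargeAreaLowGrayLevelEmphasis"] + c0 * j^2 / i^2 / n
    f["LowGrayLevelZoneEmphasis"] <- f["LowGrayLevelZoneEmphasis"] + c0 / i^2 / n
    f["SmallAreaHighGrayLevelEmphasis"] <-
      f["SmallAreaHighGrayLevelEmphasis"] + c0 * i^2 / j^2 / n
    f["SmallAreaLowGrayLevelEmphasis"] <-
      f["SmallAreaLowGrayLevelEmphasis"] + c0 / (i^2 * j^2) / n
    f["SmallAreaEmphasis"] <- f["SmallAreaEmphasis"] + c0 / j^2 / n
    f["LargeAreaHighGrayLevelEmphasis"] <-
      f["LargeAreaHighGrayLevelEmphasis"] + c0 * i^2 * j^2 / n
    f["ZoneEntropy"] <- f["ZoneEntropy"] - p[i, j] * log2(p[i, j])
    f["ZoneVariance"] <- f["ZoneVariance"] + p[i, j] * (j - mu_j)^2
  }
  f
}

oracle_percentile <- function(x, prob) {
  # linear interpolation between order statistics (R type 7), by hand
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
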