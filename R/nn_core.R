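# Minimal deterministic CPU building blocks for the two 3-D networks:
# convolution / pooling / trilinear-resize wrappers over the C++ kernels,
# group (or instance) normalization with analytic backward, ReLU/sigmoid,
# and Adam. Tensors are numeric arrays dim c(X, Y, Z, C); parameters live in
# flat named lists so the optimizer is architecture-agnostic.

# forward keeps the im2col expansion so backward can reuse it
conv3d_fw <- function(x, w, b, stride = 1L, dilation = 1L, pad = 1L,
                      keep_col = FALSE) {
  k <- dim(w)[1]
  cout <- dim(w)[5]
  od <- nn_conv_out_dim(dim(x), k, pad, stride, dilation)
  col <- nn_im2col(x, dim(x), k, pad, stride, dilation)
  wm <- matrix(w, nrow = k^3 * dim(w)[4], ncol = cout)
  y <- col %*% wm                               # (n_vox x cout), BLAS GEMM
  y <- y + rep(b, each = nrow(y))
  out <- list(y = array(y, c(od, cout)))
  if (keep_col) out$col <- col
  out
}

conv3d_bw <- function(col, xdim, w, gy, stride = 1L, dilation = 1L,
                      pad = 1L, need_gx = TRUE) {
  k <- dim(w)[1]
  cin <- dim(w)[4]
  cout <- dim(w)[5]
  gym <- matrix(gy, ncol = cout)
  gw <- crossprod(col, gym)                      # (k^3*cin x cout)
  gb <- colSums(gym)
  gx <- NULL
  if (need_gx) {
    wm <- matrix(w, nrow = k^3 * cin, ncol = cout)
    gcol <- tcrossprod(gym, wm)                  # (n_vox x k^3*cin)
    gx <- array(nn_col2im(gcol, as.integer(xdim), k, pad, stride, dilation),
                xdim)
  }
  list(gx = gx, gw = array(gw, dim(w)), gb = gb)
}

maxpool3d_fw <- function(x) {
  r <- nn_maxpool3d_fw(as.numeric(x), dim(x))
  list(y = array(r$y, r$dim), idx = r$idx, xdim = dim(x))
}

maxpool3d_bw <- function(cache, gy) {
  array(nn_maxpool3d_bw(cache$idx, as.numeric(gy), prod(cache$xdim)),
        cache$xdim)
}

resize3d_fw <- function(x, out_spatial) {
  od <- as.integer(c(out_spatial, dim(x)[4]))
  array(nn_upsample3d_fw(as.numeric(x), dim(x), od), od)
}

resize3d_bw <- function(gy, xdim) {
  array(nn_upsample3d_bw(as.numeric(gy), dim(gy), as.integer(xdim)), xdim)
}

conv_init <- function(k, cin, cout) {
  # He-normal, fan-in = k^3 * cin
  sd <- sqrt(2 / (k^3 * cin))
  list(w = array(rnorm(k^3 * cin * cout, 0, sd), dim = c(k, k, k, cin, cout)),
       b = numeric(cout))
}

norm_groups <- function(norm_kind, group_count, channels) {
  g <- if (norm_kind == "instance") channels else min(group_count, channels)
  while (channels %% g != 0) g <- g - 1L  # largest divisor <= requested
  as.integer(g)
}

gn_fw <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  S <- prod(d[1:3])
  xm <- matrix(x, S, C)
  cg <- C %/% groups
  xhat <- xm
  varg <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    v <- xm[, cols, drop = FALSE]
    mu <- mean(v)
    vg <- mean((v - mu)^2)
    varg[g] <- vg
    xhat[, cols] <- (v - mu) / sqrt(vg + eps)
  }
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(y = array(y, d),
       cache = list(xhat = xhat, varg = varg, gamma = gamma,
                    groups = groups, d = d, eps = eps))
}

gn_bw <- function(cache, gy) {
  d <- cache$d
  C <- d[4]
  S <- prod(d[1:3])
  groups <- cache$groups
  cg <- C %/% groups
  gym <- matrix(gy, S, C)
  dgamma <- colSums(gym * cache$xhat)
  dbeta <- colSums(gym)
  dxhat <- sweep(gym, 2, cache$gamma, "*")
  dx <- matrix(0, S, C)
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    xh <- cache$xhat[, cols, drop = FALSE]
    dxh <- dxhat[, cols, drop = FALSE]
    istd <- 1 / sqrt(cache$varg[g] + cache$eps)
    dx[, cols] <- istd * (dxh - mean(dxh) - xh * mean(dxh * xh))
  }
  list(gx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, mask = x > 0)
}

relu_bw <- function(mask, gy) gy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
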