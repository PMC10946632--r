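#' Survival-regression CNN and deep features
#'
#' A small convolutional network that regresses survival days directly from
#' a tumor-centred multimodal patch: four 3x3x3 convolution layers with
#' stride 2 (each followed by ReLU), a flatten, and three fully connected
#' layers whose penultimate width is fixed at 512. After training, the 512
#' penultimate activations serve as a deep-feature embedding that can be
#' fused with the radiomic features.
#'
#' @name deep_features
NULL

#' Configuration for the survival-regression CNN
#'
#' @param input_side cubic patch side in voxels (default 64; must be a
#'   multiple of 16 so four stride-2 layers divide it evenly).
#' @param conv_channels output channels of the 4 convolution stages.
#' @param fc_widths widths of the 3 fully connected layers; the second must
#'   be 512 (the deep-feature dimension) and the last 1.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (full passes over the cases).
#' @param seed RNG seed.
#' @return a `regressor_config` list.
#' @export
regressor_config <- function(input_side = 64L,
                             conv_channels = c(32L, 64L, 128L, 256L),
                             fc_widths = c(1024L, 512L, 1L),
                             learning_rate = 1e-3, epochs = 300L,
                             seed = 1L) {
  if (input_side < 16 || input_side %% 16 != 0)
    radsurv_abort("input_side must be a positive multiple of 16",
                  "radsurv_error_config")
  if (length(conv_channels) != 4)
    radsurv_abort("exactly 4 convolution stages required",
                  "radsurv_error_config")
  if (length(fc_widths) != 3 || fc_widths[2] != 512L || fc_widths[3] != 1L)
    radsurv_abort(
      "fc_widths must have 3 entries ending in 1 with penultimate 512",
      "radsurv_error_config")
  structure(list(input_side = as.integer(input_side),
                 conv_channels = as.integer(conv_channels),
                 fc_widths = as.integer(fc_widths),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "regressor_config")
}

#' Build an (untrained) survival-regression CNN
#'
#' @param cfg a [regressor_config()].
#' @param seed RNG seed for weight initialization (defaults to the config
#'   seed).
#' @return a `deep_regressor` model object.
#' @export
build_regressor <- function(cfg = regressor_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  ch <- c(4L, cfg$conv_channels)
  p <- list()
  for (i in 1:4) {
    ci <- conv_init(3L, ch[i], ch[i + 1])
    p[[paste0("conv", i, "_w")]] <- ci$w
    p[[paste0("conv", i, "_b")]] <- ci$b
  }
  flat <- (cfg$input_side %/% 16L)^3 * cfg$conv_channels[4]
  wid <- c(flat, cfg$fc_widths)
  for (i in 1:3) {
    sdv <- sqrt(2 / wid[i])
    p[[paste0("fc", i, "_w")]] <- matrix(rnorm(wid[i + 1] * wid[i], 0, sdv),
                                         wid[i + 1], wid[i])
    p[[paste0("fc", i, "_b")]] <- numeric(wid[i + 1])
  }
  structure(list(params = p, cfg = cfg), class = "deep_regressor")
}

regressor_forward <- function(model, x, train = TRUE) {
  p <- model$params
  if (!identical(dim(x), c(rep(model$cfg$input_side, 3), 4L)) &&
      !identical(dim(x), as.integer(c(rep(model$cfg$input_side, 3), 4))))
    radsurv_abort(
      sprintf("input must be %d^3 x 4", model$cfg$input_side),
      "radsurv_error_shape")
  cache <- list()
  h <- x
  for (i in 1:4) {
    cf <- conv3d_fw(h, p[[paste0("conv", i, "_w")]],
                    p[[paste0("conv", i, "_b")]], stride = 2L, pad = 1L,
                    keep_col = train)
    r <- relu_fw(cf$y)
    cache[[paste0("conv", i)]] <- list(col = cf$col, xdim = dim(h),
                                       mask = r$mask)
    h <- r$y
  }
  v <- as.numeric(h)
  cache$flat_dim <- dim(h)
  a1 <- as.numeric(p$fc1_w %*% v) + p$fc1_b
  r1 <- pmax(a1, 0)
  a2 <- as.numeric(p$fc2_w %*% r1) + p$fc2_b
  r2 <- pmax(a2, 0)                      # the 512 deep features
  out <- as.numeric(p$fc3_w %*% r2) + p$fc3_b
  cache$v <- v; cache$a1 <- a1; cache$r1 <- r1
  cache$a2 <- a2; cache$r2 <- r2
  list(out = out, features = r2, cache = if (train) cache else NULL)
}

regressor_backward <- function(model, cache, gout) {
  p <- model$params
  g <- list()
  g$fc3_w <- matrix(gout * cache$r2, 1)
  g$fc3_b <- gout
  gr2 <- as.numeric(t(p$fc3_w) * gout) * (cache$a2 > 0)
  g$fc2_w <- gr2 %o% cache$r1
  g$fc2_b <- gr2
  gr1 <- as.numeric(crossprod(p$fc2_w, gr2)) * (cache$a1 > 0)
  g$fc1_w <- gr1 %o% cache$v
  g$fc1_b <- gr1
  gh <- array(as.numeric(crossprod(p$fc1_w, gr1)), cache$flat_dim)
  for (i in 4:1) {
    cc <- cache[[paste0("conv", i)]]
    gh <- gh * cc$mask
    cb <- conv3d_bw(cc$col, cc$xdim, p[[paste0("conv", i, "_w")]], gh,
                    stride = 2L, pad = 1L, need_gx = i > 1)
    g[[paste0("conv", i, "_w")]] <- cb$gw
    g[[paste0("conv", i, "_b")]] <- cb$gb
    gh <- cb$gx
  }
  g[names(model$params)]
}

#' Train the survival-regression CNN
#'
#' Minimizes the mean squared error of predicted vs. true survival days
#' (targets standardized internally) with full-batch Adam. Seeded and
#' logged; training aborts on a non-finite loss.
#'
#' @param cases list of input patches (`input_side^3 x 4` arrays), e.g.
#'   from [prepare_regressor_input()].
#' @param os_days numeric vector of survival labels (days).
#' @param cfg a [regressor_config()].
#' @return a trained `deep_regressor` with a per-epoch `log` and the target
#'   scaling (`y_center`, `y_scale`).
#' @export
train_regressor <- function(cases, os_days, cfg = regressor_config()) {
  if (length(cases) < 2 || length(os_days) != length(cases))
    radsurv_abort("need >= 2 cases with matching labels",
                  "radsurv_error_validation")
  model <- build_regressor(cfg)
  yc <- mean(os_days)
  ys <- sd(os_days)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yt <- (os_days - yc) / ys
  st <- adam_init(model$params)
  n <- length(cases)
  log <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(cfg$epochs)) {
    grads <- NULL
    loss <- 0
    for (i in seq_len(n)) {
      fw <- regressor_forward(model, cases[[i]])
      err <- fw$out - yt[i]
      loss <- loss + err^2
      gi <- regressor_backward(model, fw$cache, 2 * err / n)
      grads <- if (is.null(grads)) gi else Map(`+`, grads, gi)
    }
    loss <- loss / n
    if (!is.finite(loss))
      radsurv_abort(sprintf("non-finite loss at epoch %d", ep),
                    "radsurv_error_numeric")
    upd <- adam_step(model$params, grads, st, cfg$learning_rate)
    model$params <- upd$params
    st <- upd$state
    log <- rbind(log, data.frame(epoch = ep, loss = loss))
  }
  model$log <- log
  model$y_center <- yc
  model$y_scale <- ys
  model
}

#' Predict survival days with the trained CNN
#'
#' @param model a trained `deep_regressor`.
#' @param x an input patch.
#' @return predicted survival in days.
#' @export
predict_survival_days <- function(model, x) {
  fw <- regressor_forward(model, x, train = FALSE)
  fw$out * (model$y_scale %||% 1) + (model$y_center %||% 0)
}

#' Extract the 512-dimensional deep-feature embedding of a case
#'
#' A pure function of the trained weights and the input (no training-mode
#' stochasticity).
#'
#' @param model a trained `deep_regressor`.
#' @param x an input patch (`input_side^3 x 4`).
#' @return numeric vector of length 512, names `deep_0001` ... `deep_0512`.
#' @export
extract_deep_features <- function(model, x) {
  fw <- regressor_forward(model, x, train = FALSE)
  setNames(fw$features, sprintf("deep_%04d", seq_along(fw$features)))
}

#' Build the tumor-centred CNN input patch for a case
#'
#' Crops the multimodal volume to the whole-tumor bounding box (with one
#' voxel of margin) and resamples each channel trilinearly to the
#' regressor's cubic input side.
#'
#' @param volume a `multimodal_volume` (typically z-score normalized).
#' @param regions a `region_channels` object (expert or predicted).
#' @param side target cubic side (default 64).
#' @return a `side^3 x 4` array.
#' @export
prepare_regressor_input <- function(volume, regions, side = 64L) {
  idx <- which(regions$wt != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    radsurv_abort("whole-tumor region is empty", "radsurv_error_validation")
  d <- dim(regions$wt)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  array(nn_upsample3d_fw(as.numeric(sub), dim(sub),
                         as.integer(c(side, side, side, 4))),
        c(side, side, side, 4))
}
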