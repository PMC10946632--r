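#' Modified 3D U-Net for tumor subregion segmentation
#'
#' A four-stage encoder-decoder. Each stage applies two 3x3x3 convolutions,
#' each followed by group (or instance) normalization and ReLU; the first
#' convolution of a stage doubles the filter count. Stages are linked by
#' 2x2x2 stride-2 max-pooling. After the deepest stage two 3x3x3 dilated
#' convolutions (rate 2) widen the receptive field and their output is
#' concatenated channel-wise with the deepest stage output. The decoder
#' mirrors the encoder using trilinear upsampling with skip concatenation at
#' equal spatial resolution, and a 1x1x1 convolution with sigmoid produces
#' three overlapping probability channels (WT, TC, ET). Training minimizes
#' the summed soft-Dice loss over the three regions.
#'
#' @name unet3d_seg
NULL

#' Network configuration for the segmenter
#'
#' @param base_filters filters of stage 1 (default 16; tests use smaller).
#' @param stages encoder depth; fixed at 4.
#' @param norm_kind `"group"` or `"instance"` normalization.
#' @param group_count groups for group normalization (default 8; reduced to
#'   the largest divisor of the channel count where needed).
#' @param dilation_rate expansion rate of the two bottleneck convolutions.
#' @param in_channels input modalities (4).
#' @param out_channels output region channels; fixed at 3.
#' @return a `unet_config` list.
#' @export
unet_config <- function(base_filters = 16L, stages = 4L,
                        norm_kind = c("group", "instance"), group_count = 8L,
                        dilation_rate = 2L, in_channels = 4L,
                        out_channels = 3L) {
  norm_kind <- match.arg(norm_kind)
  if (stages != 4L)
    radsurv_abort("encoder depth is fixed at 4 stages",
                  "radsurv_error_config")
  if (out_channels != 3L)
    radsurv_abort("the segmenter has exactly 3 output channels",
                  "radsurv_error_config")
  if (base_filters < 1)
    radsurv_abort("base_filters must be positive", "radsurv_error_config")
  structure(list(base_filters = as.integer(base_filters), stages = 4L,
                 norm_kind = norm_kind, group_count = as.integer(group_count),
                 dilation_rate = as.integer(dilation_rate),
                 in_channels = as.integer(in_channels), out_channels = 3L),
            class = "unet_config")
}

unet_channels <- function(cfg) {
  f <- cfg$base_filters
  list(enc = f * 2^(0:3), bottom = 16L * f, dec_below = c(2L * f, 4L * f,
                                                          16L * f))
}

#' Build an (untrained) segmentation network
#'
#' Initializes all convolution weights (He-normal) and normalization
#' parameters under the given seed.
#'
#' @param cfg a [unet_config()].
#' @param seed RNG seed for weight initialization.
#' @return a `unet_model` with elements `params`, `cfg`, `seed`.
#' @export
build_network <- function(cfg = unet_config(), seed = 1L) {
  set.seed(seed)
  f <- cfg$base_filters
  ch <- unet_channels(cfg)
  p <- list()
  add_block <- function(p, name, cin, cout) {
    ci <- conv_init(3L, cin, cout)
    p[[paste0(name, "_w")]] <- ci$w
    p[[paste0(name, "_b")]] <- ci$b
    p[[paste0(name, "_g")]] <- rep(1, cout)
    p[[paste0(name, "_be")]] <- rep(0, cout)
    p
  }
  for (s in 1:4) {
    cin <- if (s == 1) cfg$in_channels else ch$enc[s - 1]
    p <- add_block(p, sprintf("enc%d_c1", s), cin, ch$enc[s])
    p <- add_block(p, sprintf("enc%d_c2", s), ch$enc[s], ch$enc[s])
  }
  p <- add_block(p, "dil1", ch$enc[4], ch$enc[4])
  p <- add_block(p, "dil2", ch$enc[4], ch$enc[4])
  for (s in 3:1) {
    below <- ch$dec_below[s]
    cout <- ch$enc[s]
    p <- add_block(p, sprintf("dec%d_c1", s), below + cout, cout)
    p <- add_block(p, sprintf("dec%d_c2", s), cout, cout)
  }
  hi <- conv_init(1L, f, cfg$out_channels)
  p$head_w <- hi$w
  p$head_b <- hi$b
  structure(list(params = p, cfg = cfg, seed = as.integer(seed)),
            class = "unet_model")
}

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = array(x[, , , seq_len(n_first), drop = FALSE],
                     c(d[1:3], n_first)),
       rest = array(x[, , , (n_first + 1):d[4], drop = FALSE],
                    c(d[1:3], d[4] - n_first)))
}

ublock_fw <- function(params, name, x, cfg, dilation = 1L, train = TRUE) {
  w <- params[[paste0(name, "_w")]]
  cf <- conv3d_fw(x, w, params[[paste0(name, "_b")]],
                  dilation = dilation, pad = dilation, keep_col = train)
  groups <- norm_groups(cfg$norm_kind, cfg$group_count, dim(cf$y)[4])
  gn <- gn_fw(cf$y, params[[paste0(name, "_g")]],
              params[[paste0(name, "_be")]], groups)
  r <- relu_fw(gn$y)
  cache <- if (train)
    list(col = cf$col, xdim = dim(x), gn = gn$cache, mask = r$mask,
         dilation = dilation, name = name)
  list(y = r$y, cache = cache)
}

ublock_bw <- function(params, cache, gy, grads, need_gx = TRUE) {
  name <- cache$name
  gy <- relu_bw(cache$mask, gy)
  gnb <- gn_bw(cache$gn, gy)
  cb <- conv3d_bw(cache$col, cache$xdim, params[[paste0(name, "_w")]],
                  gnb$gx, dilation = cache$dilation, pad = cache$dilation,
                  need_gx = need_gx)
  grads[[paste0(name, "_w")]] <- grads[[paste0(name, "_w")]] + cb$gw
  grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + cb$gb
  grads[[paste0(name, "_g")]] <- grads[[paste0(name, "_g")]] + gnb$dgamma
  grads[[paste0(name, "_be")]] <- grads[[paste0(name, "_be")]] + gnb$dbeta
  list(gx = cb$gx, grads = grads)
}

unet_forward <- function(model, x, train = TRUE) {
  cfg <- model$cfg
  p <- model$params
  side <- dim(x)[1:3]
  if (any(side %% 2^(cfg$stages - 1) != 0))
    radsurv_abort(
      sprintf("input spatial extents (%s) must be divisible by %d",
              paste(side, collapse = "x"), 2^(cfg$stages - 1)),
      "radsurv_error_config")
  if (dim(x)[4] != cfg$in_channels)
    radsurv_abort("input channel count mismatch", "radsurv_error_config")
  cache <- list()
  e <- vector("list", 4)
  h <- x
  for (s in 1:4) {
    b1 <- ublock_fw(p, sprintf("enc%d_c1", s), h, cfg, train = train)
    b2 <- ublock_fw(p, sprintf("enc%d_c2", s), b1$y, cfg, train = train)
    cache[[sprintf("enc%d", s)]] <- list(b1 = b1$cache, b2 = b2$cache)
    e[[s]] <- b2$y
    if (s < 4) {
      pl <- maxpool3d_fw(b2$y)
      cache[[sprintf("pool%d", s)]] <- pl
      h <- pl$y
    }
  }
  d1 <- ublock_fw(p, "dil1", e[[4]], cfg, dilation = cfg$dilation_rate,
                  train = train)
  d2 <- ublock_fw(p, "dil2", d1$y, cfg, dilation = cfg$dilation_rate,
                  train = train)
  cache$dil <- list(b1 = d1$cache, b2 = d2$cache)
  bottom <- cat_channels(e[[4]], d2$y)
  h <- bottom
  cache$bottom_ch <- dim(e[[4]])[4]
  for (s in 3:1) {
    up <- resize3d_fw(h, dim(e[[s]])[1:3])
    cache[[sprintf("up%d", s)]] <- list(in_dim = dim(h))
    cat_in <- cat_channels(up, e[[s]])
    cache[[sprintf("cat%d", s)]] <- dim(up)[4]
    c1 <- ublock_fw(p, sprintf("dec%d_c1", s), cat_in, cfg, train = train)
    c2 <- ublock_fw(p, sprintf("dec%d_c2", s), c1$y, cfg, train = train)
    cache[[sprintf("dec%d", s)]] <- list(b1 = c1$cache, b2 = c2$cache)
    h <- c2$y
  }
  hf <- conv3d_fw(h, p$head_w, p$head_b, pad = 0L, keep_col = train)
  prob <- sigmoid(hf$y)
  cache$head_col <- hf$col
  cache$head_xdim <- dim(h)
  cache$prob <- prob
  list(prob = prob, cache = if (train) cache else NULL)
}

unet_backward <- function(model, cache, gprob) {
  cfg <- model$cfg
  p <- model$params
  grads <- lapply(p, function(q) q * 0)
  gz <- gprob * cache$prob * (1 - cache$prob)
  cb <- conv3d_bw(cache$head_col, cache$head_xdim, p$head_w, gz, pad = 0L)
  grads$head_w <- grads$head_w + cb$gw
  grads$head_b <- grads$head_b + cb$gb
  gh <- cb$gx
  gskip <- vector("list", 4)
  for (s in 1:3) {
    r2 <- ublock_bw(p, cache[[sprintf("dec%d", s)]]$b2, gh, grads)
    grads <- r2$grads
    r1 <- ublock_bw(p, cache[[sprintf("dec%d", s)]]$b1, r2$gx, grads)
    grads <- r1$grads
    sp <- split_channels(r1$gx, cache[[sprintf("cat%d", s)]])
    gskip[[s]] <- sp$rest
    gh <- resize3d_bw(sp$first, cache[[sprintf("up%d", s)]]$in_dim)
  }
  # gh is now the bottom gradient
  spb <- split_channels(gh, cache$bottom_ch)
  g_e4 <- spb$first
  r <- ublock_bw(p, cache$dil$b2, spb$rest, grads)
  grads <- r$grads
  r <- ublock_bw(p, cache$dil$b1, r$gx, grads)
  grads <- r$grads
  g_e4 <- g_e4 + r$gx
  gout <- g_e4
  for (s in 4:1) {
    if (s < 4) {
      gpool <- maxpool3d_bw(cache[[sprintf("pool%d", s)]], gout)
      gout <- gpool + gskip[[s]]
    }
    r2 <- ublock_bw(p, cache[[sprintf("enc%d", s)]]$b2, gout, grads)
    grads <- r2$grads
    r1 <- ublock_bw(p, cache[[sprintf("enc%d", s)]]$b1, r2$gx, grads,
                    need_gx = s > 1)
    grads <- r1$grads
    gout <- r1$gx
  }
  grads
}

truth_to_array <- function(truth) {
  if (inherits(truth, "region_channels"))
    return(array(c(truth$wt, truth$tc, truth$et), c(dim(truth$wt), 3)))
  truth
}

#' Summed soft-Dice loss over the WT/TC/ET channels
#'
#' Per region, the soft Dice similarity is
#' `s = (2 * sum(X*Y) + eps_num) / (sum(X^2) + sum(Y^2) + eps)` with
#' predicted probabilities `X` and binary truth `Y`; the loss is `1 - s`
#' and the total is the sum over the three regions. In the default mode the
#' smoothing term also appears in the numerator (`eps_num = eps`), which
#' makes the empty-prediction/empty-truth case a perfect score; in
#' `"strict"` mode only the denominator is smoothed, as in the plain
#' formula.
#'
#' @param pred probability array `[x, y, z, 3]` with values in `[0, 1]`,
#'   channel order WT, TC, ET.
#' @param truth a `region_channels` object or binary array of the same
#'   shape.
#' @param epsilon smoothing factor (default 1).
#' @param mode `"default"` or `"strict"`.
#' @param with_grad also return the gradient of the total loss w.r.t.
#'   `pred`.
#' @return list with `per_region` (named losses), `total`, `dice` (the
#'   similarities) and optionally `grad`.
#' @export
soft_dice_loss <- function(pred, truth, epsilon = 1,
                           mode = c("default", "strict"),
                           with_grad = FALSE) {
  mode <- match.arg(mode)
  y <- truth_to_array(truth)
  stopifnot_same_shape(pred, y, "pred and truth")
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
    radsurv_abort("pred values must lie in [0, 1]", "radsurv_error_validation")
  eps_num <- if (mode == "default") epsilon else 0
  rn <- region_names()
  loss <- numeric(3)
  dice <- numeric(3)
  grad <- if (with_grad) array(0, dim(pred)) else NULL
  for (k in 1:3) {
    X <- pred[, , , k]
    Y <- y[, , , k]
    num <- 2 * sum(X * Y) + eps_num
    den <- sum(X^2) + sum(Y^2) + epsilon
    dice[k] <- num / den
    loss[k] <- 1 - dice[k]
    if (with_grad)
      grad[, , , k] <- -(2 * Y / den - num * 2 * X / den^2)
  }
  names(loss) <- rn
  names(dice) <- rn
  out <- list(per_region = loss, total = sum(loss), dice = dice)
  if (with_grad) out$grad <- grad
  out
}

#' Training configuration for the segmenter
#'
#' @param max_iterations maximum optimizer steps (default 400).
#' @param batch_size cases per step (default 3).
#' @param learning_rate Adam step size (default 1e-4).
#' @param seed RNG seed for initialization and batch sampling.
#' @param val_every validate (and consider checkpointing) every this many
#'   steps; the checkpoint rule is fixed to minimum validation loss.
#' @param epsilon soft-Dice smoothing factor.
#' @param dice_mode `"default"` or `"strict"` numerator smoothing.
#' @return a `train_config` list.
#' @export
train_config <- function(max_iterations = 400L, batch_size = 3L,
                         learning_rate = 1e-4, seed = 1L, val_every = 10L,
                         epsilon = 1, dice_mode = "default") {
  if (max_iterations < 1 || batch_size < 1 || learning_rate <= 0)
    radsurv_abort("training configuration values must be positive",
                  "radsurv_error_config")
  structure(list(max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 val_every = as.integer(val_every), epsilon = epsilon,
                 dice_mode = dice_mode),
            class = "train_config")
}

case_tensors <- function(case) {
  list(x = case$image, y = truth_to_array(encode_regions(case$labels)))
}

#' Train the segmentation network
#'
#' Runs Adam on the summed soft-Dice loss; the returned model carries the
#' parameters of the checkpoint with minimum validation loss together with
#' a per-step training log and the RNG seed, so runs are bit-reproducible.
#'
#' @param cases list of `patch_case` training cases.
#' @param val_cases list of `patch_case` validation cases.
#' @param net_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @return a trained `unet_model` with elements `params` (best checkpoint),
#'   `log` (data frame: step, train_loss, val_loss), `best_val_loss`,
#'   `best_step`.
#' @export
train_segmenter <- function(cases, val_cases, net_cfg = unet_config(),
                            train_cfg = train_config()) {
  if (length(cases) < 1 || length(val_cases) < 1)
    radsurv_abort("need at least one training and one validation case",
                  "radsurv_error_validation")
  model <- build_network(net_cfg, seed = train_cfg$seed)
  tens <- lapply(cases, case_tensors)
  vtens <- lapply(val_cases, case_tensors)
  st <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, step = 0L)
  log <- data.frame(step = integer(), train_loss = numeric(),
                    val_loss = numeric())
  val_loss_of <- function(m) {
    mean(vapply(vtens, function(tv) {
      fw <- unet_forward(m, tv$x, train = FALSE)
      soft_dice_loss(fw$prob, tv$y, train_cfg$epsilon,
                     train_cfg$dice_mode)$total
    }, numeric(1)))
  }
  for (step in seq_len(train_cfg$max_iterations)) {
    n <- length(tens)
    bs <- train_cfg$batch_size
    idx <- sample.int(n, size = min(bs, n), replace = bs > n)
    grads <- NULL
    tloss <- 0
    for (i in idx) {
      fw <- unet_forward(model, tens[[i]]$x)
      dl <- soft_dice_loss(fw$prob, tens[[i]]$y, train_cfg$epsilon,
                           train_cfg$dice_mode, with_grad = TRUE)
      if (!is.finite(dl$total))
        radsurv_abort(sprintf("non-finite loss at step %d", step),
                      "radsurv_error_numeric")
      tloss <- tloss + dl$total
      g <- unet_backward(model, fw$cache, dl$grad)
      grads <- if (is.null(grads)) g else Map(`+`, grads, g)
    }
    grads <- lapply(grads, function(g) g / length(idx))
    tloss <- tloss / length(idx)
    upd <- adam_step(model$params, grads, st, train_cfg$learning_rate)
    model$params <- upd$params
    st <- upd$state
    vl <- NA_real_
    if (step %% train_cfg$val_every == 0 ||
        step == train_cfg$max_iterations) {
      vl <- val_loss_of(model)
      if (vl < best$loss)
        best <- list(loss = vl, params = model$params, step = step)
    }
    log <- rbind(log, data.frame(step = step, train_loss = tloss,
                                 val_loss = vl))
  }
  model$params <- best$params
  model$log <- log
  model$best_val_loss <- best$loss
  model$best_step <- best$step
  model$train_cfg <- train_cfg
  model
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint bundles the weights, configuration, RNG seed and
#' training log, so a run is fully reconstructable from the file.
#'
#' @param model a `unet_model` or `deep_regressor`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    radsurv_abort(sprintf("checkpoint not found: %s", path),
                  "radsurv_error_io")
  readRDS(path)
}

#' Predict binary region channels for a preprocessed patch
#'
#' @param model a trained `unet_model`.
#' @param x a `patch_case` or a 4-channel array.
#' @param threshold binarization threshold on the sigmoid probabilities; a
#'   probability must exceed the threshold to be foreground.
#' @param enforce_hierarchy if `TRUE`, enforce ET within TC within WT
#'   (off by default).
#' @return a `region_channels` object; the raw probability array is
#'   attached as attribute `prob`.
#' @export
predict_regions <- function(model, x, threshold = 0.5,
                            enforce_hierarchy = FALSE) {
  if (inherits(x, "patch_case")) x <- x$image
  prob <- unet_forward(model, x, train = FALSE)$prob
  wt <- (prob[, , , 1] > threshold) * 1L
  tc <- (prob[, , , 2] > threshold) * 1L
  et <- (prob[, , , 3] > threshold) * 1L
  if (enforce_hierarchy) {
    tc <- tc * wt
    et <- et * tc
  }
  out <- structure(list(wt = wt, tc = tc, et = et),
                   class = "region_channels")
  attr(out, "prob") <- prob
  out
}
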