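tiny_cfg <- function() unet_config(base_filters = 2L, group_count = 2L)

test_that("soft dice loss reproduces hand-computed values", {
  z <- array(0, c(2, 2, 2, 3))
  # strict mode, X = Y = one voxel of 1 in each channel
  p <- z; p[1, 1, 1, ] <- 1
  y <- z; y[1, 1, 1, ] <- 1
  l <- soft_dice_loss(p, y, epsilon = 1, mode = "strict")
  expect_equal(unname(l$dice), rep(2 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(l$per_region), rep(1 / 3, 3), tolerance = 1e-12)
  # disjoint one-voxel masks, strict: zero overlap
  y2 <- z; y2[2, 2, 2, ] <- 1
  l2 <- soft_dice_loss(p, y2, mode = "strict")
  expect_equal(unname(l2$dice), rep(0, 3))
  expect_equal(unname(l2$per_region), rep(1, 3))
  # default mode: empty-empty is a perfect score
  l3 <- soft_dice_loss(z, z, mode = "default")
  expect_equal(unname(l3$per_region), rep(0, 3))
  expect_equal(l3$total, 0)
  expect_error(soft_dice_loss(p, y[, , 1:1, , drop = FALSE]),
               class = "radsurv_error_shape")
})

test_that("loss gradient matches finite differences", {
  set.seed(2)
  p <- array(runif(4^3 * 3, 0.05, 0.95), c(4, 4, 4, 3))
  y <- array(rbinom(4^3 * 3, 1, 0.4), c(4, 4, 4, 3))
  l <- soft_dice_loss(p, y, with_grad = TRUE)
  for (k in 1:5) {
    i <- sample(length(p), 1)
    eps <- 1e-6
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (soft_dice_loss(pp, y)$total - soft_dice_loss(pm, y)$total) /
      (2 * eps)
    expect_equal(l$grad[i], num, tolerance = 1e-5)
  }
})

test_that("loss is bounded and monotone in true-positive probability", {
  set.seed(3)
  p <- array(runif(4^3 * 3), c(4, 4, 4, 3))
  y <- array(rbinom(4^3 * 3, 1, 0.5), c(4, 4, 4, 3))
  l <- soft_dice_loss(p, y)
  expect_true(all(l$per_region >= 0 & l$per_region <= 1))
  expect_true(l$total >= 0 && l$total <= 3)
  # raising the probability of a true-positive voxel never increases loss
  tp <- which(y == 1 & p < 0.9)[1]
  p2 <- p
  p2[tp] <- p[tp] + 0.05
  expect_lte(soft_dice_loss(p2, y)$total, l$total + 1e-12)
})

test_that("the network has the stated head, resolution ladder and range", {
  m <- build_network(tiny_cfg(), seed = 5L)
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
  fw <- unet_forward(m, x)
  expect_identical(dim(fw$prob), c(16L, 16L, 16L, 3L))   # 3 channels
  expect_true(all(fw$prob > 0 & fw$prob < 1))            # sigmoid range
  # bottleneck spatial side is input/2^3 after 3 poolings between 4 stages
  expect_identical(fw$cache$dil$b1$xdim[1:3], c(2L, 2L, 2L))
  # indivisible input side is a configuration error
  expect_error(unet_forward(m, array(0, c(12, 12, 12, 4))),
               class = "radsurv_error_config")
})

test_that("training is deterministic, checkpoints at min val loss, and
           its loss decreases on the overfit case", {
  pc <- std_patch()
  small <- list(image = pc$image[9:24, 9:24, 9:24, , drop = FALSE],
                labels = pc$labels[9:24, 9:24, 9:24])
  class(small) <- "patch_case"
  tc <- train_config(max_iterations = 50L, batch_size = 1L,
                     learning_rate = 1e-3, seed = 11L, val_every = 10L)
  m1 <- train_segmenter(list(small), list(small), tiny_cfg(), tc)
  m2 <- train_segmenter(list(small), list(small), tiny_cfg(), tc)
  expect_identical(m1$log, m2$log)                       # determinism
  expect_identical(m1$params, m2$params)
  vl <- m1$log$val_loss
  expect_equal(m1$best_val_loss, min(vl, na.rm = TRUE))  # checkpoint rule
  # checkpoint round-trip preserves the model
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m1, ck)
  m3 <- load_checkpoint(ck)
  expect_identical(m3$params, m1$params)
  expect_identical(m3$log, m1$log)
  # gradient sanity: loss decreases over the first 50 steps
  expect_lt(mean(tail(m1$log$train_loss, 10)),
            mean(head(m1$log$train_loss, 10)))
})

test_that("prediction binarizes at the threshold and can enforce nesting", {
  m <- build_network(tiny_cfg(), seed = 6L)
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
  pr <- predict_regions(m, x, threshold = 0.5, enforce_hierarchy = TRUE)
  expect_true(all(pr$et <= pr$tc) && all(pr$tc <= pr$wt))
  prob <- attr(pr, "prob")
  pr99 <- predict_regions(m, x, threshold = max(prob) + 0.01)
  expect_true(all(pr99$wt == 0))                          # strict threshold
  pr0 <- predict_regions(m, x, threshold = 0)
  expect_true(all(pr0$wt == 1))
})

test_that("training configuration defaults match the stated protocol", {
  tc <- train_config()
  expect_identical(tc$max_iterations, 400L)
  expect_identical(tc$batch_size, 3L)
  expect_equal(tc$learning_rate, 1e-4)
  expect_error(train_config(max_iterations = 0),
               class = "radsurv_error_config")
})
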