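tiny_reg_cfg <- function(epochs = 150L)
  regressor_config(input_side = 16L, conv_channels = c(4L, 8L, 16L, 32L),
                   fc_widths = c(64L, 512L, 1L), epochs = epochs, seed = 2L)

deep_cases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(8, seed = 4L)
      cache <<- list(
        cases = lapply(1:8, function(i) {
          cs <- make_phantom_case(coh$specs[[i]])
          v <- zscore_normalize(cs$volume)
          prepare_regressor_input(v, encode_regions(cs$labels), side = 16L)
        }),
        os = coh$clinical$os_days)
    }
    cache
  }
})

test_that("the regressor honors its architecture contract", {
  cfg <- tiny_reg_cfg()
  m <- build_regressor(cfg)
  x <- deep_cases()$cases[[1]]
  fw <- radsurv:::regressor_forward(m, x)
  expect_length(fw$out, 1)                      # scalar survival output
  expect_length(fw$features, 512)               # penultimate width
  # spatial side after 4 stride-2 convolutions: 16 / 2^4 = 1
  expect_identical(fw$cache$flat_dim[1:3], c(1L, 1L, 1L))
  expect_error(regressor_config(fc_widths = c(64, 256, 1)),
               class = "radsurv_error_config")
  expect_error(regressor_config(input_side = 8),
               class = "radsurv_error_config")
  expect_error(radsurv:::regressor_forward(m, array(0, c(8, 8, 8, 4))),
               class = "radsurv_error_shape")
})

test_that("the regressor overfits a small phantom cohort", {
  dc <- deep_cases()
  m <- train_regressor(dc$cases, dc$os, tiny_reg_cfg())
  preds <- vapply(dc$cases, function(x) predict_survival_days(m, x),
                  numeric(1))
  expect_lt(mean(abs(preds - dc$os)), 10)       # training MAE < 10 days
  # epoch-mean loss is non-increasing up to a 5%-of-initial tolerance
  # around its running minimum
  l <- m$log$loss
  expect_lt(tail(l, 1), head(l, 1))
  expect_true(all(l[-1] <= head(cummin(l), -1) + 0.05 * l[1]))
  # determinism: same config and seed give identical weights
  m2 <- train_regressor(dc$cases, dc$os, tiny_reg_cfg())
  expect_identical(m$params, m2$params)
})

test_that("deep features are a deterministic, sensitive embedding", {
  dc <- deep_cases()
  m <- train_regressor(dc$cases, dc$os, tiny_reg_cfg(epochs = 30L))
  f1 <- extract_deep_features(m, dc$cases[[1]])
  expect_length(f1, 512)
  expect_identical(names(f1)[1], "deep_0001")
  expect_identical(f1, extract_deep_features(m, dc$cases[[1]]))
  f2 <- extract_deep_features(m, dc$cases[[2]])
  expect_false(identical(f1, f2))               # size-sensitive
})

test_that("gradient flows through all four convolution stages", {
  dc <- deep_cases()
  m <- build_regressor(tiny_reg_cfg())
  fw <- radsurv:::regressor_forward(m, dc$cases[[1]])
  g <- radsurv:::regressor_backward(m, fw$cache, 1)
  for (i in 1:4)
    expect_gt(sqrt(sum(g[[paste0("conv", i, "_w")]]^2)), 0)
})
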