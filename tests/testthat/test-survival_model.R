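test_that("standardization matches the sample-sd formula and drops constants", {
  x <- cbind(a = c(0, 10), b = c(3, 5))
  s <- standardize(x)
  expect_equal(s$Z[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # already-standardized input is unchanged
  z2 <- standardize(s$Z)
  expect_equal(z2$Z, s$Z, tolerance = 1e-12)
  xc <- cbind(a = rnorm(5), const = rep(7, 5))
  expect_warning(s3 <- standardize(xc), "constant")
  expect_identical(s3$dropped, "const")
  expect_identical(colnames(s3$Z), "a")
})

test_that("the correlation matrix is Z'Z/(n-1) with unit diagonal", {
  m <- corr_fixture()
  Z <- standardize(m)$Z
  R <- correlation_matrix(Z)
  expect_equal(diag(R), c(f1 = 1, f2 = 1), tolerance = 1e-10)
  expect_equal(R[1, 2], 0.6, tolerance = 1e-10)
  expect_equal(R[1, 2], cor(m[, 1], m[, 2]), tolerance = 1e-10)
  # duplicated column gives off-diagonal 1
  R2 <- correlation_matrix(cbind(Z[, 1], Z[, 1]))
  expect_equal(R2[1, 2], 1, tolerance = 1e-12)
})

test_that("PCA reproduces the closed-form two-feature solution", {
  m <- corr_fixture(r = 0.6)
  p <- pca_fit(m, t = 0.8)
  expect_equal(unname(p$values), c(1.6, 0.4), tolerance = 1e-10)
  expect_equal(sum(p$values), 2, tolerance = 1e-10)        # trace identity
  expect_identical(p$m, 1L)                                # 0.8 reached at k=1
  expect_identical(pca_fit(m, t = 1)$m, 2L)                # t = 1 keeps all
  # a single direction of variation explains everything
  u <- rnorm(30)
  m1 <- cbind(a = u, b = 2 * u)
  suppressWarnings(p1 <- pca_fit(m1, t = 0.5))
  expect_equal(p1$contrib[1], 1, tolerance = 1e-10)
  expect_identical(p1$m, 1L)
})

test_that("component scores satisfy the PCA identities", {
  set.seed(61)
  x <- matrix(rnorm(200 * 6), 200, 6)
  x[, 2] <- x[, 1] * 0.7 + x[, 2]
  colnames(x) <- paste0("f", 1:6)
  p <- pca_fit(x, t = 1)
  sc <- pca_transform(p, x)
  expect_equal(unname(apply(sc, 2, var)), unname(p$values),
               tolerance = 1e-6)
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # eigenvectors orthonormal
  B <- p$vectors
  expect_equal(crossprod(B), diag(6), tolerance = 1e-8, ignore_attr = TRUE)
  # transforming the training mean row gives zero scores
  mu <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_equal(unname(pca_transform(p, mu)[1, ]), rep(0, 6),
               tolerance = 1e-10)
  # reconstruction with m = p recovers the standardized data
  Z <- standardize(x)$Z
  expect_equal(sc %*% t(B), Z, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_transform(p, x[, 1:3]),
               class = "radsurv_error_validation")
})

test_that("the variance-weighted composite is the stated weighted sum", {
  m <- corr_fixture(r = 0.6)
  p <- pca_fit(m, t = 1)                        # lambda = {1.6, 0.4}, m = 2
  u <- matrix(c(2, -1), 1)
  expect_equal(variance_weighted_composite(p, u), (1.6 * 2 - 0.4 * 1) / 2,
               tolerance = 1e-9)
  expect_equal(variance_weighted_composite(p, matrix(0, 1, 2)), 0)
})

test_that("the design matrix fuses scores with encoded clinical columns", {
  sc <- matrix(rnorm(4 * 5), 4, 5,
               dimnames = list(NULL, paste0("pc_0", 1:5)))
  clin <- data.frame(case_id = letters[1:4], age = c(50, 60, 70, 55),
                     grade = c("HGG", "LGG", "HGG", "HGG"),
                     os_days = 1:4)
  ad <- assemble_design_matrix(sc, clin)
  expect_identical(ncol(ad$X), 7L)              # 5 scores + age + grade dummy
  expect_identical(colnames(ad$X)[6:7], c("age", "grade_LGG"))
  ad2 <- assemble_design_matrix(sc, clin)
  expect_identical(colnames(ad$X), colnames(ad2$X))  # deterministic order
  clin_bad <- clin
  clin_bad$age[2] <- NA
  expect_error(assemble_design_matrix(sc, clin_bad),
               class = "radsurv_error_validation")
  expect_error(assemble_design_matrix(sc[1:3, ], clin),
               class = "radsurv_error_validation")
})

test_that("SVR obeys the epsilon-tube and reproduces its own expansion", {
  # constant target: flat solution inside the tube
  X <- matrix(seq(0, 1, length.out = 20), ncol = 1,
              dimnames = list(NULL, "x"))
  mc <- svr_fit(X, rep(42, 20), kernel = "linear")
  expect_equal(svr_predict(mc, X), rep(42, 20), tolerance = 1e-6)
  # noiseless linear data, small epsilon, large cost
  y <- 2 * X[, 1] + 1
  ml <- svr_fit(X, y, kernel = "linear", cost = 1000, epsilon = 0.01)
  expect_lte(max(abs(svr_predict(ml, X) - y)), 0.02)
  # the kernel expansion evaluates identically to predict
  set.seed(71)
  Xr <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  yr <- Xr %*% c(1, -2, 0.5) + rnorm(20, 0, 0.1)
  mr <- svr_fit(Xr, as.numeric(yr))
  expect_equal(svr_decision_function(mr, Xr), svr_predict(mr, Xr),
               tolerance = 1e-8)
  # permutation and duplication behave elementwise
  perm <- c(5:1, 6:20)
  expect_equal(svr_predict(mr, Xr[perm, ]), svr_predict(mr, Xr)[perm])
  expect_equal(svr_predict(mr, Xr[c(1, 1), ]),
               rep(svr_predict(mr, Xr[1, , drop = FALSE]), 2))
  expect_error(svr_fit(Xr[c(1, 1), ], c(1, 2)),
               class = "radsurv_error_validation")
})

test_that("survival-error metrics match their formulas", {
  expect_equal(os_error_metrics(c(1, 2), c(1, 2)),
               list(mse = 0, mae = 0, rmse = 0))
  m <- os_error_metrics(c(100, 200), c(110, 190))
  expect_equal(m$mse, 100)
  expect_equal(m$mae, 10)
  expect_equal(m$rmse, 10)
  set.seed(81)
  o <- rnorm(50); p <- rnorm(50)
  mm <- os_error_metrics(o, p)
  expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-10)
  expect_error(os_error_metrics(numeric(0), numeric(0)),
               class = "radsurv_error_validation")
})

test_that("SVR recovers the phantom survival model and improves with n", {
  coh200 <- make_cohort(200, seed = 13L)
  coh50 <- make_cohort(50, seed = 13L)
  heldout_mae <- function(coh, ntr) {
    X <- coh$truth$features[, -1]
    tr <- seq_len(ntr)
    te <- setdiff(seq_len(nrow(X)), tr)
    fit <- fit_survival_model(X[tr, ], coh$clinical[tr, ], t = 0.95)
    pred <- predict_survival(fit, X[te, ], coh$clinical[te, ])
    mean(abs(pred - coh$clinical$os_days[te]))
  }
  mae200 <- heldout_mae(coh200, 160)
  mae50 <- heldout_mae(coh50, 40)
  expect_lte(mae200, 60)                        # <= 2x noise sd (30 days)
  expect_lt(mae200, mae50)
})

test_that("cyclic cross-validation is reproducible, complete and leak-free", {
  coh <- make_cohort(40, seed = 17L)
  X <- coh$truth$features[, -1]
  cv <- cyclic_cross_validate(X, coh$clinical, repeats = 25L, seed = 19L)
  expect_identical(nrow(cv$per_repeat), 25L)
  expect_equal(cv$aggregate$mae, mean(cv$per_repeat$mae))
  expect_equal(cv$aggregate$mse, mean(cv$per_repeat$mse))
  cv2 <- cyclic_cross_validate(X, coh$clinical, repeats = 25L, seed = 19L)
  expect_identical(cv$per_repeat, cv2$per_repeat)
  # leakage probe: perturbing a repeat's test-only case leaves that
  # repeat's fitted state and training predictions untouched
  cvm <- cyclic_cross_validate(X, coh$clinical, repeats = 2L, seed = 19L,
                               keep_models = TRUE)
  probe_idx <- cvm$models[[1]]$test_idx[1]
  X2 <- X
  X2[probe_idx, ] <- X2[probe_idx, ] * 100 + 1e5
  cvm2 <- cyclic_cross_validate(X2, coh$clinical, repeats = 2L,
                                seed = 19L, keep_models = TRUE)
  expect_identical(cvm$models[[1]]$test_idx, cvm2$models[[1]]$test_idx)
  m1 <- cvm$models[[1]]$model
  m2 <- cvm2$models[[1]]$model
  expect_equal(m1$pca$values, m2$pca$values)
  expect_equal(m1$pca$vectors, m2$pca$vectors)
  expect_equal(m1$svr$fit$coefs, m2$svr$fit$coefs)
  expect_equal(m1$svr$fit$rho, m2$svr$fit$rho)
  expect_error(cyclic_cross_validate(X[1:5, ], coh$clinical[1:5, ]),
               class = "radsurv_error_validation")
})
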