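#' PCA feature selection and SVR survival prediction
#'
#' Feature selection standardizes the case-by-feature table (sample sd,
#' denominator n-1), forms the feature correlation matrix `R = Z'Z/(n-1)`,
#' and eigendecomposes it; components are retained until the cumulative
#' explained-variance fraction reaches the threshold `t`. The selected
#' component scores (or their variance-weighted composite) are fused with
#' clinical covariates and fed to epsilon-insensitive support vector
#' regression of survival days. Accuracy is reported as MSE, MAE and RMSE
#' under repeated random 90/10 cross-validation.
#'
#' @name survival_model
NULL

#' Standardize a case-by-feature table
#'
#' Columns are centred and scaled to unit sample standard deviation
#' (denominator n-1, matching the correlation convention `Z'Z/(n-1)`).
#' Constant columns cannot be standardized and are dropped with a warning.
#'
#' @param x numeric matrix or data frame (cases in rows).
#' @return a list with `Z` (standardized matrix), `center`, `scale`, and
#'   `dropped` (names of constant columns).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    radsurv_abort("need at least 2 cases", "radsurv_error_validation")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- is.finite(scl) & scl > 0
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    warning(sprintf("dropping %d constant column(s): %s", length(dropped),
                    paste(head(dropped, 5), collapse = ", ")))
  Z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep], "-"), 2,
             scl[keep], "/")
  list(Z = Z, center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' Feature correlation matrix `R = Z'Z / (n - 1)`
#'
#' @param Z a standardized matrix (from [standardize()]).
#' @return the p x p correlation matrix (symmetric, unit diagonal).
#' @export
correlation_matrix <- function(Z) {
  crossprod(as.matrix(Z)) / (nrow(Z) - 1)
}

#' Fit the PCA feature-selection model
#'
#' Eigendecomposition of the feature correlation matrix. Eigenvalues are
#' returned in descending order (their sum equals the number of retained
#' features, the trace of `R`); each unit eigenvector's sign is fixed so
#' its largest-magnitude component is positive. The retained count `m` is
#' the smallest `k` whose cumulative explained-variance fraction reaches
#' `t`.
#'
#' @param x raw case-by-feature matrix, or an already-standardized matrix
#'   with `standardized = TRUE`.
#' @param t explained-variance threshold in `(0, 1]` (default 0.95).
#' @param standardized set when `x` is already standardized.
#' @return a `pca_model`: `center`, `scale`, `R` (the correlation matrix;
#'   `NULL` when p > n, where it is never formed), `values` (eigenvalues),
#'   `vectors`, `m`, `t`, `contrib` (variance contribution rates).
#' @export
pca_fit <- function(x, t = 0.95, standardized = FALSE) {
  if (t <= 0 || t > 1)
    radsurv_abort("t must be in (0, 1]", "radsurv_error_config")
  if (standardized) {
    Z <- as.matrix(x)
    ctr <- rep(0, ncol(Z))
    scl <- rep(1, ncol(Z))
    names(ctr) <- names(scl) <- colnames(Z)
  } else {
    s <- standardize(x)
    Z <- s$Z
    ctr <- s$center
    scl <- s$scale
  }
  if (ncol(Z) <= nrow(Z)) {
    R <- correlation_matrix(Z)
    ee <- eigen(R, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    vecs <- ee$vectors
  } else {
    # p > n: R has rank < n, so its nonzero eigenvalues (which still sum to
    # p, the trace) come cheaply from the SVD of Z without forming the
    # p x p matrix
    sv <- svd(Z)
    vals <- pmax(sv$d^2 / (nrow(Z) - 1), 0)
    vecs <- sv$v
    R <- NULL
  }
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  frac <- cumsum(vals) / sum(vals)
  m <- which(frac >= t - 1e-12)[1]
  rownames(vecs) <- colnames(Z)
  structure(list(center = ctr, scale = scl, R = R, values = vals,
                 vectors = vecs, m = m, t = t,
                 contrib = vals / sum(vals)),
            class = "pca_model")
}

#' Project cases onto the retained principal components
#'
#' Scores are the standardized rows multiplied by the unit eigenvectors;
#' on the training set the score variance of component `j` equals its
#' eigenvalue and scores are mutually uncorrelated.
#'
#' @param model a `pca_model`.
#' @param x case-by-feature matrix with the training feature set.
#' @return an `n x m` matrix of component scores.
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(x)
  miss <- setdiff(names(model$center), colnames(x))
  if (length(miss))
    radsurv_abort(sprintf("missing feature(s): %s",
                          paste(head(miss, 5), collapse = ", ")),
                  "radsurv_error_validation")
  xs <- x[, names(model$center), drop = FALSE]
  Z <- sweep(sweep(xs, 2, model$center, "-"), 2, model$scale, "/")
  sc <- Z %*% model$vectors[, seq_len(model$m), drop = FALSE]
  colnames(sc) <- sprintf("pc_%02d", seq_len(model$m))
  sc
}

#' Variance-weighted composite of the retained component scores
#'
#' `sum_j (lambda_j / sum(lambda)) * U_j` over the `m` retained components.
#'
#' @param model a `pca_model`.
#' @param scores score matrix from [pca_transform()].
#' @return one composite value per case.
#' @export
variance_weighted_composite <- function(model, scores) {
  w <- model$contrib[seq_len(model$m)]
  as.numeric(as.matrix(scores) %*% w)
}

#' Assemble the SVR design matrix from selected features and clinical data
#'
#' Mode `"scores"` keeps the `m` component scores; `"composite"` collapses
#' them to the variance-weighted composite. Clinical covariates are
#' appended: numeric columns as-is, categorical columns dummy-encoded
#' (first level as reference). Missing clinical values are an error; there
#' is no silent imputation.
#'
#' @param selected score matrix (or composite vector) with one row per
#'   case, in `clinical` row order.
#' @param clinical data frame with `case_id` and covariate columns (any of
#'   `os_days` is ignored here).
#' @param mode `"scores"` or `"composite"`.
#' @param levels_map optional named list fixing factor levels (used at
#'   predict time for a training-time encoding).
#' @return a list with `X` (numeric design matrix) and `levels_map`.
#' @export
assemble_design_matrix <- function(selected, clinical,
                                   mode = c("scores", "composite"),
                                   levels_map = NULL) {
  mode <- match.arg(mode)
  sel <- as.matrix(selected)
  if (nrow(sel) != nrow(clinical))
    radsurv_abort("case count mismatch between features and clinical table",
                  "radsurv_error_validation")
  covars <- setdiff(colnames(clinical), c("case_id", "os_days"))
  base <- if (mode == "composite") {
    matrix(sel[, 1], ncol = 1, dimnames = list(NULL, "composite"))
  } else sel
  out <- base
  lm_out <- list()
  for (cv in covars) {
    v <- clinical[[cv]]
    if (anyNA(v))
      radsurv_abort(sprintf("missing clinical value in column %s", cv),
                    "radsurv_error_validation")
    if (is.numeric(v)) {
      out <- cbind(out, setNames(data.frame(v), cv))
    } else {
      lev <- levels_map[[cv]] %||% sort(unique(as.character(v)))
      bad <- setdiff(unique(as.character(v)), lev)
      if (length(bad))
        radsurv_abort(sprintf("unseen level(s) in %s: %s", cv,
                              paste(bad, collapse = ", ")),
                      "radsurv_error_validation")
      lm_out[[cv]] <- lev
      for (l in lev[-1]) {
        cn <- paste0(cv, "_", l)
        out <- cbind(out, setNames(data.frame((v == l) * 1), cn))
      }
    }
  }
  X <- as.matrix(out)
  rownames(X) <- NULL
  list(X = X, levels_map = lm_out)
}

#' Fit epsilon-insensitive support vector regression
#'
#' Wraps libsvm (via e1071) with predictors and targets standardized
#' internally. The fitted state is the kernel expansion
#' `f(x) = sum_i w_i k(x_i, x) + b`; [svr_decision_function()] evaluates
#' that expansion explicitly.
#'
#' @param X numeric design matrix.
#' @param y survival days.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost constraint-violation cost C (default 100).
#' @param epsilon insensitive-tube half-width on the standardized target
#'   (default 0.1).
#' @param gamma RBF kernel width (default `1/ncol(X)`).
#' @return an `svr_model`.
#' @export
svr_fit <- function(X, y, kernel = c("radial", "linear"), cost = 100,
                    epsilon = 0.1, gamma = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (nrow(X) < 2)
    radsurv_abort("need at least 2 cases", "radsurv_error_validation")
  if (any(!is.finite(y)))
    radsurv_abort("non-finite targets", "radsurv_error_validation")
  if (nrow(unique(X)) == 1)
    radsurv_abort("degenerate design: all rows identical",
                  "radsurv_error_validation")
  gamma <- gamma %||% 1 / ncol(X)
  if (sd(y) == 0) {
    # a constant target lies entirely inside the epsilon tube; the optimal
    # flat solution is the constant itself
    return(structure(list(fit = NULL, constant = y[1],
                          columns = colnames(X), kernel = kernel,
                          cost = cost, epsilon = epsilon, gamma = gamma),
                     class = "svr_model"))
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = TRUE)
  structure(list(fit = fit, columns = colnames(X), kernel = kernel,
                 cost = cost, epsilon = epsilon, gamma = gamma),
            class = "svr_model")
}

#' Predict survival days from a fitted SVR model
#'
#' @param model an `svr_model`.
#' @param X design matrix with the training columns.
#' @param clamp_nonnegative floor predictions at 0 days (off by default).
#' @return numeric predictions (days).
#' @export
svr_predict <- function(model, X, clamp_nonnegative = FALSE) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$columns))
    radsurv_abort("design-matrix columns do not match the fitted model",
                  "radsurv_error_validation")
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  p <- as.numeric(predict(model$fit, X))
  if (clamp_nonnegative) p <- pmax(p, 0)
  p
}

#' Evaluate the fitted kernel expansion explicitly
#'
#' Reconstructs `f(x) = sum_i w_i k(x_i, x) + b` from the stored support
#' vectors, dual coefficients and offset (undoing libsvm's internal
#' scaling), independently of `predict`.
#'
#' @param model an `svr_model`.
#' @param X design matrix.
#' @return numeric predictions (days).
#' @export
svr_decision_function <- function(model, X) {
  fit <- model$fit
  X <- as.matrix(X)[, model$columns, drop = FALSE]
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  xs <- X
  if (any(fit$scaled)) {
    ctr <- fit$x.scale$`scaled:center`
    scl <- fit$x.scale$`scaled:scale`
    xs[, fit$scaled] <- sweep(sweep(X[, fit$scaled, drop = FALSE], 2, ctr,
                                    "-"), 2, scl, "/")
  }
  sv <- fit$SV
  co <- as.numeric(fit$coefs)
  kv <- switch(model$kernel,
    radial = {
      d2 <- outer(rowSums(xs^2), rowSums(sv^2), "+") - 2 * xs %*% t(sv)
      exp(-fit$gamma * pmax(d2, 0))
    },
    linear = xs %*% t(sv)
  )
  f_scaled <- as.numeric(kv %*% co) - fit$rho
  if (!is.null(fit$y.scale)) {
    f_scaled * fit$y.scale$`scaled:scale` + fit$y.scale$`scaled:center`
  } else f_scaled
}

#' Survival-error metrics: MSE, MAE, RMSE
#'
#' @param obs,pred observed and predicted survival days (equal, nonzero
#'   length).
#' @return list with `mse`, `mae`, `rmse`.
#' @export
os_error_metrics <- function(obs, pred) {
  if (length(obs) == 0 || length(obs) != length(pred))
    radsurv_abort("obs and pred must be nonempty and of equal length",
                  "radsurv_error_validation")
  e <- obs - pred
  list(mse = mean(e^2), mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Fit the full survival pipeline on a training set
#'
#' standardize -> PCA (threshold `t`) -> fuse with clinical -> SVR.
#'
#' @param features numeric case-by-feature matrix (no id column).
#' @param clinical clinical data frame aligned row-wise with `features`;
#'   must contain `os_days`.
#' @param t PCA explained-variance threshold.
#' @param mode `"scores"` or `"composite"` fusion of the PCA output.
#' @param kernel,cost,epsilon SVR settings (see [svr_fit()]).
#' @return a `survival_model` bundling the fitted PCA, encoding and SVR
#'   states.
#' @export
fit_survival_model <- function(features, clinical, t = 0.95,
                               mode = c("scores", "composite"),
                               kernel = "radial", cost = 100,
                               epsilon = 0.1) {
  mode <- match.arg(mode)
  if (is.null(clinical$os_days))
    radsurv_abort("clinical table must contain os_days",
                  "radsurv_error_validation")
  pca <- pca_fit(as.matrix(features), t = t)
  sc <- pca_transform(pca, as.matrix(features))
  sel <- if (mode == "composite") {
    matrix(variance_weighted_composite(pca, sc), ncol = 1,
           dimnames = list(NULL, "composite"))
  } else sc
  ad <- assemble_design_matrix(sel, clinical, mode = "scores")
  svr <- svr_fit(ad$X, clinical$os_days, kernel = kernel, cost = cost,
                 epsilon = epsilon)
  structure(list(pca = pca, mode = mode, levels_map = ad$levels_map,
                 svr = svr, columns = colnames(ad$X)),
            class = "survival_model")
}

#' Predict survival days for new cases with a fitted pipeline
#'
#' @param model a `survival_model` from [fit_survival_model()].
#' @param features case-by-feature matrix with the training feature set.
#' @param clinical clinical covariates aligned row-wise with `features`.
#' @return numeric predictions (days).
#' @export
predict_survival <- function(model, features, clinical) {
  sc <- pca_transform(model$pca, as.matrix(features))
  sel <- if (model$mode == "composite") {
    matrix(variance_weighted_composite(model$pca, sc), ncol = 1,
           dimnames = list(NULL, "composite"))
  } else sc
  ad <- assemble_design_matrix(sel, clinical, mode = "scores",
                               levels_map = model$levels_map)
  svr_predict(model$svr, ad$X)
}

#' Repeated random-split (cyclic) cross-validation of OS prediction
#'
#' Each repeat draws a fresh random 90/10 train/test split from a
#' per-repeat seed derived from the master seed, fits the whole pipeline
#' (standardize, PCA, clinical fusion, SVR) on the training fold only, and
#' evaluates MSE/MAE/RMSE on the held-out fold. Nothing fitted ever sees
#' the test fold.
#'
#' @param features case-by-feature matrix or data frame (an optional
#'   `case_id` column is used for alignment with `clinical`).
#' @param clinical clinical data frame with `case_id`, covariates and
#'   `os_days`.
#' @param repeats number of repeats (default 100).
#' @param train_frac training fraction (default 0.9).
#' @param seed master seed.
#' @param t,mode,kernel,cost,epsilon pipeline settings.
#' @param keep_models also return the per-repeat fitted models and test
#'   indices (for leakage probes).
#' @return a `cv_report`: `per_repeat` data frame (repeat, seed, mse, mae,
#'   rmse), `aggregate` (means), `config`, and optionally `models`.
#' @export
cyclic_cross_validate <- function(features, clinical, repeats = 100L,
                                  train_frac = 0.9, seed = 1L, t = 0.95,
                                  mode = "scores", kernel = "radial",
                                  cost = 100, epsilon = 0.1,
                                  keep_models = FALSE) {
  fdf <- as.data.frame(features, check.names = FALSE)
  if ("case_id" %in% colnames(fdf)) {
    if (!identical(as.character(fdf$case_id),
                   as.character(clinical$case_id)))
      radsurv_abort("case_id mismatch between features and clinical",
                    "radsurv_error_validation")
    fdf$case_id <- NULL
  }
  fm <- as.matrix(fdf)
  n <- nrow(fm)
  if (n < 10)
    radsurv_abort("need at least 10 cases for 90/10 splitting",
                  "radsurv_error_validation")
  n_test <- max(1L, round(n * (1 - train_frac)))
  if (n_test >= n)
    radsurv_abort("train fraction leaves no training cases",
                  "radsurv_error_validation")
  rows <- vector("list", repeats)
  models <- if (keep_models) vector("list", repeats)
  for (r in seq_len(repeats)) {
    rs <- derive_seed(seed, r)
    set.seed(rs)
    test_idx <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), test_idx)
    # constant-column warnings from per-fold standardization would repeat
    # `repeats` times; folds legitimately drop such columns
    fit <- suppressWarnings(
      fit_survival_model(fm[tr, , drop = FALSE],
                         clinical[tr, , drop = FALSE], t = t,
                         mode = mode, kernel = kernel, cost = cost,
                         epsilon = epsilon))
    pred <- predict_survival(fit, fm[test_idx, , drop = FALSE],
                             clinical[test_idx, , drop = FALSE])
    met <- os_error_metrics(clinical$os_days[test_idx], pred)
    rows[[r]] <- data.frame(repeat_id = r, seed = rs, mse = met$mse,
                            mae = met$mae, rmse = met$rmse)
    if (keep_models)
      models[[r]] <- list(model = fit, test_idx = test_idx)
  }
  per <- do.call(rbind, rows)
  out <- list(per_repeat = per,
              aggregate = list(mse = mean(per$mse), mae = mean(per$mae),
                               rmse = mean(per$rmse)),
              config = list(repeats = repeats, train_frac = train_frac,
                            seed = seed, t = t, mode = mode,
                            kernel = kernel, cost = cost,
                            epsilon = epsilon))
  if (keep_models) out$models <- models
  structure(out, class = "cv_report")
}
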