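#' End-to-end pipeline orchestration
#'
#' Runs the full survival-prediction workflow on a case manifest: load and
#' preprocess each case (z-score normalization, lesion-centred crop), train
#' or apply the segmenter, evaluate segmentation metrics against the expert
#' labels, extract radiomic features, and cross-validate the PCA + SVR
#' survival model. All artifacts are written under a run directory together
#' with a reproducibility manifest (seeds, configuration digest).
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' @param manifest path of a case-manifest CSV with columns case_id, t1,
#'   t1ce, t2, flair, seg, age, grade, os_days.
#' @param out_dir run directory for all artifacts.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param patch_side cropping patch side (default 128; phantom-scale runs
#'   use less).
#' @param net_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @param feature_cfg a [feature_config()].
#' @param cv_repeats,cv_train_frac cross-validation protocol.
#' @param pca_t PCA explained-variance threshold.
#' @param use_predicted_masks extract features from the segmenter's
#'   predictions (`TRUE`) or the expert labels (`FALSE`, default).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, out_dir, seed = 1L, patch_side = 128L,
                            net_cfg = unet_config(),
                            train_cfg = train_config(),
                            feature_cfg = feature_config(
                              fixed_bin_count = 32),
                            cv_repeats = 100L, cv_train_frac = 0.9,
                            pca_t = 0.95, use_predicted_masks = FALSE) {
  structure(list(manifest = manifest, out_dir = out_dir,
                 seed = as.integer(seed),
                 patch_side = as.integer(patch_side), net_cfg = net_cfg,
                 train_cfg = train_cfg, feature_cfg = feature_cfg,
                 cv_repeats = as.integer(cv_repeats),
                 cv_train_frac = cv_train_frac, pca_t = pca_t,
                 use_predicted_masks = use_predicted_masks),
            class = "pipeline_config")
}

pipeline_log <- function(stage, msg, ...) {
  message(sprintf("[radsurv:%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the run artifacts: `metrics`
#'   (segmentation metrics data frame), `features` (wide feature table),
#'   `cv` (the `cv_report`), `predictions` (per-case predicted OS), and
#'   the artifact file paths.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mf <- read.csv(cfg$manifest, stringsAsFactors = FALSE)
  req <- c("case_id", "t1", "t1ce", "t2", "flair", "seg", "age", "grade",
           "os_days")
  miss <- setdiff(req, colnames(mf))
  if (length(miss))
    radsurv_abort(sprintf("manifest lacks column(s): %s",
                          paste(miss, collapse = ", ")),
                  "radsurv_error_validation")
  # stage 1: preprocess
  cases <- list()
  for (i in seq_len(nrow(mf))) {
    id <- mf$case_id[i]
    loaded <- tryCatch(
      load_case(c(mf$t1[i], mf$t1ce[i], mf$t2[i], mf$flair[i]), mf$seg[i]),
      error = function(e) radsurv_abort(
        sprintf("stage preprocess failed for case %s: %s", id,
                conditionMessage(e)), "radsurv_error_stage"))
    vol <- zscore_normalize(loaded$volume)
    pc <- crop_case(vol, loaded$labels, side = cfg$patch_side)
    cases[[id]] <- pc
    pipeline_log("preprocess", "case %s cropped at offset %s", id,
                 paste(pc$crop_offset, collapse = ","))
  }
  # stage 2: segmentation (train on all, validate on all: phantom-scale)
  tc <- cfg$train_cfg
  tc$seed <- derive_seed(cfg$seed, 1L)
  model <- train_segmenter(cases, cases, cfg$net_cfg, tc)
  pipeline_log("segment", "best validation loss %.4f at step %d",
               model$best_val_loss, model$best_step)
  utils::write.csv(model$log, file.path(cfg$out_dir, "training_log.csv"),
                   row.names = FALSE)
  save_checkpoint(model, file.path(cfg$out_dir, "segmenter_checkpoint.rds"))
  # stage 3: predict masks + metrics
  met_rows <- list()
  pred_regions <- list()
  for (id in names(cases)) {
    pr <- predict_regions(model, cases[[id]])
    pred_regions[[id]] <- pr
    truth <- encode_regions(cases[[id]]$labels)
    met <- evaluate_case(pr, truth, spacing = cases[[id]]$spacing)
    met$case_id <- id
    met_rows[[id]] <- met
    lab <- decode_regions(pr)
    img <- RNifti::asNifti(lab)
    RNifti::pixdim(img) <- cases[[id]]$spacing
    RNifti::writeNifti(img, file.path(cfg$out_dir,
                                      paste0(id, "_pred_seg.nii.gz")))
  }
  metrics <- do.call(rbind, met_rows)
  metrics <- metrics[, c("case_id", "region", "dice", "sensitivity",
                         "specificity", "haus95_mm", "abd_mm")]
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  # stage 4: features
  feat_cases <- lapply(names(cases), function(id) {
    regions <- if (cfg$use_predicted_masks) pred_regions[[id]] else
      encode_regions(cases[[id]]$labels)
    list(volume = cases[[id]]$image, regions = regions)
  })
  features <- extract_cohort_features(feat_cases, cfg$feature_cfg,
                                      case_ids = names(cases))
  utils::write.csv(features, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)
  long <- data.frame(case_id = rep(features$case_id, ncol(features) - 1),
                     feature = rep(colnames(features)[-1],
                                   each = nrow(features)),
                     value = as.numeric(as.matrix(features[, -1])))
  utils::write.csv(long, file.path(cfg$out_dir, "features_long.csv"),
                   row.names = FALSE)
  pipeline_log("features", "%d features per case", ncol(features) - 1)
  # stage 5: survival CV + refit on all cases
  clinical <- mf[, c("case_id", "age", "grade", "os_days")]
  fm <- as.matrix(features[, -1])
  keep <- apply(fm, 2, function(v) all(is.finite(v)))
  fm <- fm[, keep, drop = FALSE]
  cv <- cyclic_cross_validate(fm, clinical, repeats = cfg$cv_repeats,
                              train_frac = cfg$cv_train_frac,
                              seed = derive_seed(cfg$seed, 2L),
                              t = cfg$pca_t)
  jsonlite::write_json(
    list(per_repeat = cv$per_repeat, aggregate = cv$aggregate,
         config = cv$config),
    file.path(cfg$out_dir, "cv_report.json"), auto_unbox = TRUE,
    digits = NA)
  fit <- suppressWarnings(fit_survival_model(fm, clinical, t = cfg$pca_t))
  preds <- data.frame(case_id = clinical$case_id,
                      os_days_true = clinical$os_days,
                      os_days_pred = predict_survival(fit, fm, clinical))
  utils::write.csv(preds, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  pipeline_log("survival", "CV MAE %.1f days over %d repeats",
               cv$aggregate$mae, cfg$cv_repeats)
  # reproducibility manifest
  jsonlite::write_json(
    list(seed = cfg$seed,
         derived_seeds = list(segmenter = derive_seed(cfg$seed, 1L),
                              crossval = derive_seed(cfg$seed, 2L)),
         patch_side = cfg$patch_side,
         net_cfg = unclass(cfg$net_cfg),
         train_cfg = unclass(cfg$train_cfg),
         feature_cfg = unclass(cfg$feature_cfg),
         cv = list(repeats = cfg$cv_repeats,
                   train_frac = cfg$cv_train_frac, pca_t = cfg$pca_t),
         package_version = as.character(utils::packageVersion("radsurv"))),
    file.path(cfg$out_dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(metrics = metrics, features = features, cv = cv,
                 predictions = preds,
                 paths = file.path(cfg$out_dir,
                                   c("metrics.csv", "features.csv",
                                     "predictions.csv", "cv_report.json",
                                     "run_manifest.json"))))
}

#' Describe the feature and metric registry
#'
#' Prints every feature category with its count and names; optionally
#' returns the machine-readable registry.
#'
#' @param json return a JSON string instead of printing.
#' @return the registry data frame (invisibly), or a JSON string.
#' @export
describe_registry <- function(json = FALSE) {
  reg <- feature_registry()
  if (json) {
    return(jsonlite::toJSON(split(reg$name, reg$category),
                            auto_unbox = FALSE))
  }
  for (k in unique(reg$category)) {
    nm <- reg$name[reg$category == k]
    cat(sprintf("%s (%d): %s\n", k, length(nm), paste(nm, collapse = ", ")))
  }
  invisible(reg)
}
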