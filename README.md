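# radsurv

Non-invasive overall-survival (OS) prediction for glioblastoma from
multimodal brain MRI, implemented as a single, fully testable R package.
It is aimed at methods researchers and students who want to study — and
verify, stage by stage — a complete radiomics survival pipeline without
downloading multi-gigabyte challenge datasets or training on GPUs:
every stage runs at desk scale on synthetic phantoms with known ground
truth.

## What it implements

**Segmentation.** A modified 3D U-Net segments the three nested tumor
subregions — whole tumor (WT), tumor core (TC), enhancing tumor (ET) —
from the four MRI sequences (T1, T1ce, T2, FLAIR). Four encoder stages
of paired 3×3×3 convolutions with group/instance normalization, 2×2×2
stride-2 max-pooling, two dilation-2 convolutions at the bottleneck
(concatenated with the deepest stage), a trilinear-upsampling decoder
with skip connections, and a 1×1×1 head with three sigmoid channels.
Training minimizes the summed soft-Dice loss

    loss = Σ_r [ 1 − (2 Σ X_r Y_r + ε) / (Σ X_r² + Σ Y_r² + ε) ],  ε = 1

over r ∈ {WT, TC, ET} with Adam (batch 3, lr 1e-4, ≤ 400 steps,
min-validation-loss checkpoint). The 3-D convolution/pooling/resampling
kernels and their exact adjoints are implemented in C++ (convolution as
GEMM over an im2col expansion) — no deep-learning framework is needed.

**Evaluation.** Dice = 2TP/(FP+2TP+FN), sensitivity, specificity, the
95th-percentile Hausdorff distance and the average boundary
displacement, per subregion, spacing-aware (mm).

**Features.** A from-scratch radiomic bank: shape (14), first-order
(18), GLCM (22), GLRLM (16), GLSZM (16), GLDM (14) and interpolated
statistics (9), computed per modality and region on the original image
and its eight single-level 3-D wavelet sub-bands (periodized orthogonal
db4). A small survival-regression CNN (four stride-2 convolutions +
three fully connected layers) exposes a 512-dimensional deep-feature
embedding.

**Survival model.** Features are standardized (Z = (x−x̄)/s), the
correlation matrix R = ZᵀZ/(n−1) is eigendecomposed, and components are
retained until the cumulative explained variance reaches t (default
0.95). Scores (or their variance-weighted composite Σ λ_j/Σλ · U_j) are
fused with clinical covariates (age, grade) and fed to ε-insensitive
support vector regression, f(x) = Σ ω_i k(x_i, x) + b. Accuracy is
reported as MSE / MAE / RMSE under 100 repeats of random 90/10
cross-validation.

**Phantoms.** `make_phantom_case()` / `make_cohort()` generate nested
ellipsoidal tumors with modality-specific contrasts, plus survival times
from a known linear model of tumor volumes, age and grade — so
segmentation, metrics, features and the survival model are all testable
against constructible truth.

## Worked example

Generate a 12-case phantom cohort, run the full pipeline (preprocess →
train segmenter → predict masks → metrics → 9570 radiomic features →
PCA + SVR with 20× cross-validation):

```r
library(radsurv)
coh      <- make_cohort(12, seed = 42)
manifest <- write_cohort(coh, "example_data")
cfg <- pipeline_config(
  manifest, "example_run", seed = 42, patch_side = 32,
  net_cfg   = unet_config(base_filters = 4),
  train_cfg = train_config(max_iterations = 600, learning_rate = 1e-3,
                           val_every = 50),
  cv_repeats = 20)
res <- run_pipeline(cfg)
head(res$metrics[res$metrics$region == "wt", ], 4)
res$cv$aggregate
```

which prints (abridged; ~15 minutes on one CPU):

```
[radsurv:segment] best validation loss 0.8660 at step 600
[radsurv:features] 9570 features per case
[radsurv:survival] CV MAE 48.3 days over 20 repeats
     case_id region  dice sensitivity haus95_mm abd_mm
 phantom_001     wt 0.888       0.801      4.24  0.615
 phantom_002     wt 0.907       0.831      4.58  0.659
 phantom_003     wt 0.868       0.777      3.32  0.572
 phantom_004     wt 0.906       0.829      5.10  0.718
CV over 20 repeats: MAE 48.3 days, RMSE 48.3 days
```

Reading the numbers: after 600 training steps on 12 cases the
whole-tumor masks overlap the expert phantom labels with Dice ≈ 0.9
and sub-voxel average boundary error; the cross-validated survival
error of ≈ 48 days sits against a survival-generating noise floor of
30 days on OS times spanning roughly 100–550 days. (With 12 cases each
90/10 test fold holds a single case, so per-repeat MAE and RMSE
coincide.) The run directory contains the predicted masks (NIfTI),
`metrics.csv`, `features.csv`, `predictions.csv`, `cv_report.json` and
a `run_manifest.json` recording every seed and setting needed to
reproduce the run bit-identically.

Individual stages are plain functions: `zscore_normalize()`,
`crop_case()`, `train_segmenter()`, `predict_regions()`,
`evaluate_case()`, `extract_case_features()`, `train_regressor()`,
`extract_deep_features()`, `pca_fit()`, `svr_fit()`,
`cyclic_cross_validate()`. A thin command-line front end lives at
`inst/cli/radsurv.R` (`phantom`, `run`, `evaluate`, `registry`).

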