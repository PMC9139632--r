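# bmseg — detection and segmentation of small brain metastases

`bmseg` is an R implementation of a deep-learning pipeline for detecting
and segmenting brain metastases (BM) on contrast-enhanced T1 MR volumes,
built for the regime where it is hardest: lesions mostly below 0.1 cc on
high-resolution (≈ 0.195 × 0.195 × 1 mm³) acquisitions, where a metastasis
covers a vanishing fraction of a 1024 × 1024 slice. It targets radiation
oncology workflows (gross-tumor-volume delineation for stereotactic
ablative radiotherapy) and methodologists who want a fully tested,
self-contained reference of the 2.5D overlapping-patch technique.

The core method:

* **2.5D overlapping patches** — 128 × 128 windows slid at a 64-pixel
  stride (225 windows per 1024 × 1024 slice); the five consecutive axial
  slices *z−2 … z+2* form the network's five input channels.
* **Balanced training** — healthy windows are undersampled and tumor
  windows resampled to 30 000 each; flips, rotations, blur and random
  gamma are applied on the fly. The 2D U-Net uses ELU activations with
  batch normalisation before each activation, and is optimised with Adam
  (L2 β = 1e-5), learning rate 1e-4 halved on a 2-epoch validation
  plateau, ≤ 30 epochs, batch 256.
* **Probability averaging** — every pixel's probability is the arithmetic
  mean of all overlapping window predictions.
* **Lesion-level evaluation** — candidate lesions are 26-connected
  components ≥ 0.02 cc; metrics are

  $$\mathrm{Sens} = \frac{TP}{TP+FN},\qquad
    \mathrm{FP/patient} = \frac{\sum_i FP_i}{N},\qquad
    \mathrm{DICE} = \frac{2|GT\cap PR|}{|GT|+|PR|},$$

  plus DWD (Dice after dilating both masks by a physical 3 mm sphere,
  the clinically tolerated contour margin) and the directed 95th-percentile
  Hausdorff distance HD95 in mm.

No public patient dataset exists for this setting, so the package includes
a synthetic head-phantom generator (bright brain ellipsoid, skewed-small
hyperintense lesions, vessel-like false-positive bait, bias field, noise)
that makes every stage testable end to end. The U-Net itself — layers,
backpropagation, Adam, LR schedule — is implemented in the package on C++
im2col/GEMM kernels and verified by numerical-gradient and overfit tests.

## Worked example

A complete phantom study — simulate, train briefly, predict, evaluate —
on desk-scale volumes (40 × 256 × 256 at (1, 0.78, 0.78) mm):

```r
library(bmseg)

spec <- phantom_spec(shape = c(40, 256, 256), spacing = c(1, 0.78, 0.78),
                     n_lesions = 8, lesion_volume_range_cc = c(0.01, 0.8),
                     lesion_contrast = 2.0, noise_sigma = 0.03,
                     bias_amplitude = 0.15, seed = 101)
ph <- generate_phantom(spec)
ph$lesions
#> <lesion_set> 8 ground_truth lesion(s), volumes 0.01034-0.4247 cc

img  <- scale_intensity(correct_bias_field(ph$image))
grid <- plan_grid(256, 256, patch_size = 32, stride = 16)
idx  <- index_patches(img, ph$gt, grid)
pool <- materialize_pool(balance_pool(idx, per_class_target = 400, seed = 42))

model <- build_unet(unet_spec(in_channels = 5, depth = 3, base_filters = 8,
                              patch_size = 32), seed = 42)
fit <- train_model(model, pool,
                   train_config(initial_lr = 1e-3, max_epochs = 5,
                                batch_size = 16, seed = 42))

test <- generate_phantom(phantom_spec(shape = c(40, 256, 256),
                                      spacing = c(1, 0.78, 0.78),
                                      n_lesions = 8, seed = 901))
prob <- predict_volume(fit$model, scale_intensity(correct_bias_field(test$image)), grid)
post <- postprocess_prediction(prob, threshold = 0.5, min_volume_cc = 0.02)
rep  <- metrics_report(list(evaluate_case(test$gt, post$mask)))
rep$summary
```

On the study used by the acceptance script (8 training + 2 test phantoms,
seed 1) this prints a per-bin table whose Total row reads

```
volume_bin n_lesions sensitivity_pct n_fps  dice   dwd  hd95_mm
     Total        16            87.5     9 0.654 0.746    1.391
```

with sensitivity 100 % for the lesions ≥ 0.04 cc: all losses are among the
sub-0.04 cc (few-voxel) lesions, mirroring the clinical difficulty
ordering. `dice`/`dwd` are per-lesion means; `n_fps` counts predicted
components overlapping no true lesion (mostly vessel bait).

The same pipeline is scriptable from a shell via `exec/bmseg`
(`simulate`, `preprocess`, `patchify`, `train`, `predict`, `evaluate`,
`end2end`), with a YAML `--config` whose defaults equal the reference
protocol values (patch 128, stride 64, context 2, LR 1e-4, factor 0.5,
patience 2, 30 epochs, β 1e-5, threshold 0.5, 0.02 cc minimum volume, 3 mm
margin), and a provenance JSON written next to every output.

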