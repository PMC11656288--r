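# wavetta

Source-free, **single-sample test-time adaptation (TTA)** for 3D medical
image segmentation in R. A V-Net-style volumetric segmenter is augmented
with **multilevel discrete-wavelet-transform (DWT) sub-band attention**;
at test time, for each unlabeled volume independently, only the sub-band
attention gates and the batch-normalization affine parameters are tuned by
an unsupervised hybrid objective, starting fresh from the source checkpoint
for every sample. The package is self-contained on a CPU: it ships a
seeded synthetic phantom benchmark with controllable intensity domain
shifts, so the whole pipeline is runnable and testable without external
data. It targets researchers studying domain shift and test-time
adaptation for volumetric (MR) organ segmentation.

## Method in brief

For a volume `X` with per-voxel foreground probability `P_i(X, theta)`:

* **Model.** Encoder stage *n + 1* receives, alongside the pooled spatial
  features, the eight level-*n* DWT sub-bands of `X` (orthonormal
  Daubechies filters, periodized; `LLL` + 7 high-pass combinations), each
  scaled by a learned sigmoid gate from a **sub-band attention (SA)**
  block (global pool → FC → FC → sigmoid), projected by a 1×1×1
  convolution and concatenated. A single-channel sigmoid head yields `P`.
* **Source phase.** Train the segmenter with the
  soft Dice loss (batch size 1); record the class-ratio prior
  `F̂s = mean per-sample foreground fraction` of the training labels;
  harvest early-stopped snapshots to generate *undertrained*
  segmentations; train the **Refine** autoencoder `Rf` to map them to
  their ground-truth labels (MSE).
* **Adaptation.** Freeze all parameters except SA + BN affine;
  for 200 SGD steps (lr 5e-4) on the single test volume minimize

  `L_total = 0.5 * L_en + 1.0 * L_sh + L_re`

  where `L_en` is the mean binary Shannon entropy of `(P, 1-P)`, `L_sh`
  the symmetrized Bernoulli-KL between the soft foreground ratio
  `Fs = mean(P)` and the prior `F̂s`, and `L_re = mean((Rf(P) - P)^2)`
  with `Rf` frozen. BN layers use the test volume's own statistics.
* **Evaluation.** Dice coefficient and HD95 (95th percentile of pooled
  bidirectional boundary distances, mm).

There is no deep-learning framework in the dependency stack: convolutions
are GEMM-backed `im2col` kernels (Rcpp/Armadillo) with hand-derived,
finite-difference-verified backward passes.

## Worked example

```r
library(wavetta)

# a seeded benchmark: 8 source phantoms, 10 shifted targets (24x24x16)
bench <- make_benchmark(n_source = 8, n_target = 10,
                        shift = shift_preset("strong"), seed = 1,
                        extents = c(24, 24, 16))

cfg   <- wavnet_config(stages = 3, encoder_channels = c(4, 8, 16),
                       proj_channels = 2)
model <- withr::with_seed(11, build_wavnet(cfg))
fit   <- train_source(model,
                      lapply(bench$source, `[[`, "volume"),
                      lapply(bench$source, `[[`, "label"),
                      source_config(epochs = 120, learning_rate = 0.01,
                                    seed = 11))

corpus <- generate_undertrained_segmentations(
  lapply(bench$source, `[[`, "volume"),
  lapply(bench$source, `[[`, "label"),
  schedule = c(5, 8, 12, 16, 20, 24),
  config = source_config(epochs = 25, learning_rate = 0.01, seed = 12),
  model_config = cfg)
refine <- train_refine(withr::with_seed(13,
            build_refine_model(refine_config(depth = 2, channels = c(4, 8)))),
          corpus, epochs = 25, learning_rate = 0.02, seed = 13)

ck <- list(model = fit$model, prior = fit$prior)
t1 <- bench$target[[2]]
res <- adapt_single_sample(ck, refine$model, t1$target_volume,
                           tta_config(iterations = 200))
c(before = dice_coefficient(binarize(res$baseline_prob), t1$label),
  after  = dice_coefficient(binarize(res$prob),          t1$label))
```

On this seed the run prints

```
   before     after
0.5034072 0.7524904
```

i.e. the unadapted source model reaches Dice 0.50 on the shifted volume
and single-sample adaptation lifts it to 0.75 after 200 iterations.
Across the ten targets of
this benchmark the source model loses ≈ 52 Dice points to the strong shift
and adaptation recovers ≈ 20 points on average (10/10 samples improved);
`res$trace` holds the per-iteration `L_en / L_sh / L_re / L_total` values
for loss-curve plots.

## Command line

```sh
Rscript -e 'wavetta::wavetta_cli()' simulate --out runs/data --preset strong \
    --seed 0 --extents 24x24x16 --n-source 8 --n-target 10
Rscript -e 'wavetta::wavetta_cli()' train-source --data runs/data --out runs/src \
    --config inst/examples/desk.yaml
Rscript -e 'wavetta::wavetta_cli()' make-undertrained --data runs/data --out runs/und \
    --config inst/examples/desk.yaml
Rscript -e 'wavetta::wavetta_cli()' train-refine --corpus runs/und/corpus.rds \
    --out runs/rf --config inst/examples/desk.yaml
Rscript -e 'wavetta::wavetta_cli()' adapt --checkpoint runs/src/checkpoint.rds \
    --refine runs/rf/refine.rds --volume runs/data/target_01_target.nii.gz \
    --out runs/adapt
Rscript -e 'wavetta::wavetta_cli()' evaluate --pred runs/adapt/segmentation.nii.gz \
    --label runs/data/target_01_label.nii.gz
Rscript -e 'wavetta::wavetta_cli()' ablation --data runs/data \
    --checkpoint runs/src/checkpoint.rds --refine runs/rf/refine.rds \
    --out runs/abl --iterations 20
```

`inst/examples/desk.yaml` is the CPU profile used throughout the tests;
`inst/examples/fullscale.yaml` is the full-scale profile (GPU-class compute).
NIfTI (`.nii`/`.nii.gz`) volumes are read and written natively.

## Further reading

`vignettes/wavetta-methods.Rmd` documents the model and objective in
detail, the numerical conventions, what the synthetic benchmark does and
does not emulate, and the design decisions taken where the method
description left choices open.
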