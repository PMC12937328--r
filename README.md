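# pointid

Non-contact individual identification of livestock from overhead depth
imaging. The package implements, end to end in R, a point-cloud
classification network for dorsal (back-surface) scans together with its
full experimental pipeline: depth-frame projection, resampling,
augmentation, leakage-safe session-level splitting, training, evaluation,
ablation and neighborhood-sweep runners, an analytic complexity profiler,
and a synthetic dorsal-surface generator for controlled experiments.

## The model

Each animal's back, seen from a fixed overhead depth camera, is an
unordered set of 3-D points `X ∈ R^{N×3}`. Identity lives in smooth
geometry — spine curvature along the body axis and undulations at
shoulders and hips. The classifier is a staged residual point-MLP; each
stage:

1. selects center points by farthest point sampling (greedy max–min);
2. groups each center's neighborhood through two parallel branches —
   exact k-nearest neighbors, and a *stochastically dilated* branch that
   draws k neighbors uniformly from the 2k-nearest candidate shell —
   concatenated along the neighbor dimension into a 2k-wide group;
3. normalizes grouped features with a learnable geometric affine
   (per-group standard deviation, per-channel scale/shift);
4. transforms per-neighbor edge features
   `concat(center, neighbor, Δxyz)` with a shared MLP and residual
   blocks, then max-pools over the 2k neighbors;
5. recalibrates channels with a squeeze-and-excitation gate
   (`C → C/8 → C`, sigmoid); and
6. refines center features with further residual blocks.

In the efficient (`full`) variant the residual blocks use *partial
convolutions*: only the first ⌈C/4⌉ channels are convolved (cost ratio
(1/4)² = 1/16 per layer); the rest pass through unchanged. Training uses
SGD (momentum 0.9), cosine-annealed learning rate, label smoothing 0.1,
scale/translate/shuffle augmentation (no rotation — clouds are
gravity-aligned), and early stopping on validation overall accuracy.
Metrics are overall accuracy (OA) and mean class accuracy (mAcc) from the
confusion matrix.

Forward and backward passes are written natively (BLAS-backed matrix code
with a few compiled kernels); gradients are verified against finite
differences in the test suite.

## Worked example

Generate a small synthetic herd, train the full variant, and evaluate:

The run below (about five minutes on one CPU) is the package's desk-scale
reference experiment: four synthetic individuals, 150 clouds each, whole
recording sessions held out for testing.

```r
library(pointid)

herd  <- synthetic_config(num_classes = 4, per_class = 150,
                          points_per_cloud = 1024, sessions_per_class = 5,
                          seed = 2024)
ds    <- generate_synthetic(herd)
prep  <- prepare_dataset(ds, 128, seed = 1)       # resample + unit sphere
split <- video_level_split(prep, 0.8, seed = 1)   # whole sessions only

net <- model_config(input_points = 128, stage_points = c(64, 32),
                    stage_channels = c(32, 64), embedding_channels = 16,
                    pre_blocks = 1, pos_blocks = 1, k = 6, num_classes = 4,
                    classifier_hidden = 32, variant = "full")
fit <- train_model(build_model(net, seed = 42), split$train,
                   val_samples = split$test,
                   cfg = train_config(lr0 = 0.02, lr_min = 1e-4,
                                      max_epochs = 30,
                                      early_stop_patience = 29, seed = 42))
rep <- evaluate_model(fit$model, split$test)
rep
#> <metrics_report> OA = 0.9250 | mAcc = 0.9250 | 4 classes
rep$per_class_acc
#> [1] 0.9000000 0.9333333 0.9333333 0.9333333
```

The report's `oa` is the fraction of test clouds assigned to the right
individual; `macc` averages per-class accuracies, so it is robust to class
imbalance; `confusion` holds the full count matrix (true classes on rows).
Sessions never straddle the train/test boundary, so the accuracy is free
of temporal leakage from near-duplicate frames.

Profile the full-scale architecture (parameters and per-sample FLOPs, 1
multiply-accumulate = 2 FLOPs):

```r
profile_model(model_config(variant = "baseline"), resolutions = c(1024, 2048))
#>    variant   params  flops_1024  flops_2048
#> 1 baseline 13253898 31245079552 62488843264
```

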