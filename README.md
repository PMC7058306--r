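# cytogan

Two-step training of a benign/malignant lung-cytology patch classifier
with progressively grown GANs, in R.

Labeled cytology patches are expensive: microscope fields are focused
manually, and every patch from a malignant case needs cytopathologist
review. `cytogan` implements a pipeline for this low-data regime:
microscope fields are tiled into non-overlapping 256 x 256 patches and
labeled through an expert selection table; the training set is expanded by
rotation/flip/color-gain augmentation plus two focus-variation filters; one
progressively grown Wasserstein GAN per class synthesizes additional
images; a VGG-style classifier with a new 1024/256/2 fully connected head
is pretrained end to end on the synthetic images and then fine-tuned on the
real patches with all convolutional weights frozen; performance is reported
as a confusion matrix at a 0.5 malignancy cut-off, sensitivity/specificity/
accuracy, and tie-grouped trapezoidal ROC/AUC under a holdout plus
threefold cross-validation protocol.

At its core are three pieces, all implemented (and unit-verified against
independent oracles) in the package:

* **Progressive growth** — the generator starts from a 128-value latent at
  4 x 4 and doubles resolution per stage (512 feature maps up to 16 px,
  then 256/128/64/32), blending each new block in with a linear fade-in
  coefficient `alpha = min(step / fade_steps, 1)`; training minimizes the
  Wasserstein objective `L_D = E[D(x_fake)] - E[D(x_real)]`,
  `L_G = -E[D(x_fake)]` with a weight-clipped critic.
* **Sliced Wasserstein distance** — generated-image quality metric:
  the average over random unit projections of the 1-D Wasserstein-1
  distance between projected sample sets.
* **Two-step transfer** — pretraining updates every parameter on
  GAN-labeled images; fine-tuning updates only the fully connected head
  (the conv freeze is bitwise). AUC equals the Mann-Whitney statistic by
  construction.

A seeded synthetic-cytology generator (ellipse cell clumps with
class-dependent nucleus size, N:C ratio and chromatin texture, plus focus
blur) stands in for the private clinical data, so the entire pipeline is
reproducible offline.

## Worked example

Evaluation arithmetic on a 620-patch cross-validated prediction set whose
confusion counts are 261 true-benign, 45 false-malignant, 46 false-benign
and 268 true-malignant:

```r
library(cytogan)
m <- confusion_counts(tn = 261, fp = 45, fn = 46, tp = 268)
round(summary_metrics(m), 3)
#> sensitivity specificity    accuracy
#>       0.854       0.853       0.853
```

A method-comparison table with deltas against generic (ImageNet-style)
pretraining:

```r
cmp <- method_comparison(list(
  ImageNet = c(sensitivity = 0.850, specificity = 0.768,
               accuracy = 0.810, auc = 0.872),
  DCGAN    = c(sensitivity = 0.793, specificity = 0.797,
               accuracy = 0.795, auc = 0.867),
  PGGAN    = c(sensitivity = 0.854, specificity = 0.853,
               accuracy = 0.853, auc = 0.901)))
cmp$deltas[cmp$deltas$method == "PGGAN", c("accuracy", "specificity")]
#>   accuracy specificity
#> 3    0.043       0.085
```

So GAN-based pretraining is worth +4.3 accuracy points and +8.5
specificity points over the generic baseline on that prediction set.

The full pipeline at desk scale — synthetic 32 x 32 patches, a two-stage
progressive GAN per class, `vgg_tiny` backbone, pretrain-then-fine-tune:

```r
r <- two_step_experiment(seed = 1)
r$accuracy   # held-out accuracy, e.g. 0.983 on 60 held-out patches
r$auc        # held-out AUC, e.g. 1.0
r$gan_log$malignant   # per-stage d_loss / g_loss / SWD / gradient penalty
```

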