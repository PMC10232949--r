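# masunet

Zonal segmentation of prostate MRI with an attention-gated U-Net,
implemented from scratch in R.

Automatic delineation of the prostate's **transition zone** (TZ) and
**peripheral zone** (PZ) on T2-weighted MRI supports staging and therapy
monitoring, and replaces a slow, operator-dependent manual task. This
package implements a U-shaped convolutional network for that task:

- encoder of five convolution blocks — two rounds of (3×3 conv → **group
  normalization** → ReLU) each — with 2×2 max pooling between them and
  channel dropout (p = 0.5) in the deepest block;
- an **ASPP** bottleneck: parallel 3×3 dilated convolutions at rates
  1/6/12/18, concatenated and fused by a 1×1 convolution;
- a decoder of four scales of nearest-neighbour up-convolution with
  **dual attention gates** on the skip connections — a per-pixel spatial
  coefficient `α = σ(W₂ ReLU(Wₓx + W_g g))` and a squeeze-excitation style
  per-channel coefficient `β = σ(W₁W₀ ReLU(gap(x) + gap(g)))`, gating the
  skip as `α·β·x`;
- two sigmoid output channels (PZ, TZ) trained with the **BCE + soft-dice**
  compound loss, and Dice / PPV / sensitivity evaluation pooled per volume.

Everything — forward passes, backpropagation through every layer, Adam,
early stopping — is implemented in the package (R + `RcppArmadillo` C++
kernels for the convolutions), with no deep-learning framework. Every
layer's gradient is verified against finite differences in the test suite.
The data layer reads and writes NIfTI volumes in the Medical Segmentation
Decathlon (MSD) Task05 layout, and a synthetic prostate-phantom generator
stands in for the real dataset so the whole pipeline runs end-to-end with
no external download.

## Worked example

Generate a phantom dataset, train a small network briefly, and evaluate:

```r
library(masunet)

vols  <- generate_phantom_dataset(phantom_config(n_volumes = 4,
                                                 slices_per_volume = 4,
                                                 seed = 1))
split <- split_dataset(vols, fraction = 0.75, seed = 2)

net <- build_masunet(masunet_config(base_channels = 8), seed = 3)
net
#> <masunet> base 8, in 1, classes 2, ASPP rates 1/6/12/18, 710,826 parameters (seed 3)

fit <- train_model(net, split,
                   train_config(seed = 4, max_epochs = 3, patience = 20),
                   target_size = c(64, 64),
                   aug_cfg = augmentation_config(seed = 5))
round(fit$state$history, 4)
#>   epoch train_loss val_loss val_mean_dice val_dice_pz val_dice_tz
#> 1     1     1.4916   1.4255        0.3882      0.6013      0.1751
#> 2     2     1.3719   1.3854        0.3987      0.6018      0.1957
#> 3     3     1.3281   1.3432        0.4353      0.6164      0.2541

ev <- evaluate_model(fit$net, split$validation, target_size = c(64, 64))
ev$summary
#>   class      dice       ppv sensitivity
#> 1    PZ 0.6164053 0.4641235   0.9174147
#> 2    TZ 0.2541030 0.1455429   1.0000000
```

Three epochs on three tiny volumes is only a smoke run: the network has
found the gland (high sensitivity for both zones) but still over-predicts
each zone's extent, and the metrics climb steadily with every epoch. An
overfit run under the same recipe reaches high Dice on both zones within a
few hundred optimizer steps (`scripts/acceptance.R` reports that run's Dice
at 200 and 600 steps — see the methods vignette). Each
history row is one epoch: the mean training-batch loss, the validation
loss, and per-zone validation Dice pooled per volume. `evaluate_model`
reports Dice, positive predictive value and sensitivity per class, averaged
over validation volumes.

Predictions for a volume, written as NIfTI plus PNG overlays (green PZ,
red TZ):

```r
lab <- predict_volume(fit$net, vols[[4]], target_size = c(64, 64),
                      out_path = "pred.nii.gz", overlay_dir = "overlays")
table(lab)
#> lab
#>    0    1    2 
#> 9935  739 5710
```

A thin command-line front end with `generate-synthetic`, `train`,
`evaluate`, `predict` and `augment` subcommands lives at
`inst/cli/masunet.R` (after installation:
`Rscript $(Rscript -e 'cat(system.file("cli/masunet.R", package="masunet"))') train --data DIR --out RUN`).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "masunet",
                               load_package = "installed")'
```

The suite covers oracle equivalence of every numerical primitive (group
normalization, softmax/cross-entropy, dice losses, attention gates) on tiny
inputs, finite-difference gradient checks through the whole network, the
architecture's shape and gate-reduction contracts, augmentation and split
invariants, determinism, and an overfit training run.

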