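# dnlseg — deformed non-local networks for blood vessel segmentation

`dnlseg` segments thin, curvilinear blood vessels in 2D medical images
(CT-angiography slices, retinal fundus patches) with a U-shaped
encoder–decoder built around three attention modules:

* **DNL (deformed non-local)** — standard non-local self-attention compares
  every spatial position with every other, so the attention–value product of
  a `C × H × W` map costs `C·(HW)²` multiply-accumulates.  DNL replaces it
  with a channel-similarity attention
  `A = softmax(θ(x) φ(x)ᵀ) ∈ R^{C̄×C̄}`, followed by a descriptor bottleneck
  and a squeeze-and-excitation gate, cutting that product to `HW·C̄²` —
  a reduction of exactly `HW/C̄`.
* **MFF (multi-scale feature fusion)** — decoder fusion
  `MFF = AV(DNL(x_deep)) ⊙ x_skip + UP(x_deep)`, where
  `AV = σ(Conv₁ₓ₁(Normalize(GAP(·))))` is a channel attention vector gating
  the encoder skip feature.
* **RSEP (residual SE pyramid pooling)** — four parallel 3×3 atrous
  convolutions (dilations 1/6/12/12) each with an SE gate, concatenated with
  the input and fused back, widening the receptive field at the bottleneck.

Training uses ADAM (β₁ = 0.5, β₂ = 0.999), initial learning rate 1e-3 with
per-epoch polynomial decay `(1 − (epoch−1)/total)^0.9`, and a
Dice + weighted cross-entropy loss.  Evaluation covers soft/hard Dice, mean
IoU, sensitivity/specificity/accuracy, ROC AUC, and a connected-component
filter that removes islands below 0.03% of the segmented foreground.

Because clinical vessel datasets are private or external, the package ships
a seeded generator of curvilinear vessel phantoms with exact masks
(`generate_phantom()`); every claim in the test suite runs on phantoms.
There is no deep-learning framework dependency: the package contains its own
tape-based reverse-mode autodiff engine with compiled (Rcpp/RcppArmadillo)
convolution kernels, and its gradients are verified against finite
differences in the tests.

## Worked example

```r
library(dnlseg)

## attention geometry: positional (HW x HW) vs channel (C x C)
x <- array(runif(16 * 8 * 8), c(16, 8, 8))
dim(nl_attention(x, nl_weights(16, seed = 1)))    # 64 64
dim(dnl_attention(x, dnl_weights(16, seed = 1)))  # 16 16
fg_product_op_counts(Cbar = 16, H = 96, W = 96)$ratio  # 576

## simulate a small corpus of CTA-style phantoms and train the test preset
train <- generate_dataset(32, phantom_spec(preset = "cta"), seed = 7)
dataset <- lapply(train, function(p) list(image = p$image, mask = p$mask))
net <- dnl_net(dnlnet_config(preset = "test"), seed = 1)
net <- dnlnet_train(net, dataset,
                    train_config(preset = "test", total_epochs = 10, seed = 1))
summary(net)
#> DNL-Net (2 stages, base width 8, 43,494 parameters)
#>   input channels: 1; output classes: 1
#>   RSEP dilations: 1/6/12/12; MFF upsampling: bilinear
#>   trained
#> Training: 10 epochs; final lr 0.000126
#>   best validation soft Dice: 0.6361 (epoch 10)

## segment a fresh phantom and score it against its exact mask
ph <- generate_phantom(phantom_spec(preset = "cta", seed = 999))
prob <- predict(net, ph$image)
round(unlist(metrics_report(prob, ph$mask)), 4)
#>   dice_soft        dice    mean_iou sensitivity specificity    accuracy
#>      0.6085      0.6883      0.6790      0.9876      0.8351      0.8591
#>         auc
#>      0.9668
dice_coefficient(baseline_segment(ph$image), ph$mask)
#> [1] 0.4279507
```

`dice_soft` is the Dice overlap of the raw probability map with the exact
phantom mask; `dice`/`mean_iou` score the 0.5-thresholded mask; `auc` is the
pixelwise Mann–Whitney AUC.  The phantoms are deliberately low-contrast
(vessel-to-background contrast 0.3 against noise 0.18), so even this short
run beats the classical Otsu-threshold + component-filter baseline
(`baseline_segment()`, Dice 0.43 on this phantom); the shipped end-to-end
check trains longer (128 phantoms, 30 epochs) and reaches a held-out soft
Dice near 0.89.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/dnlseg.R synth --preset cta --n 32 --seed 7 --out phantoms
Rscript inst/cli/dnlseg.R train --data phantoms --out run --preset test --seed 1
Rscript inst/cli/dnlseg.R predict --model run/checkpoint.rds --input phantoms --out pred --postprocess
Rscript inst/cli/dnlseg.R evaluate --pred pred/prob/phantom_0001.tiff \
        --mask phantoms/masks/phantom_0001.png --out metrics.json --roc roc.csv
```

## Package layout

* `R/autodiff.R` — tape-based reverse-mode autodiff over `(N,C,H,W)` arrays
* `src/kernels.cpp` — im2col+GEMM convolution, batched matmul, pooling,
  channel broadcasts, connected-component labelling
* `R/blocks.R`, `R/fusion.R` — SE/NL/DNL blocks, MFF, RSEP
* `R/network.R` — `dnl_net()`, `predict()`, S3 methods
* `R/training.R` — losses, schedule, preprocessing, augmentation, ADAM loop
* `R/evaluation.R` — metrics and post-processing
* `R/phantom.R` — the phantom generator and classical baseline
* `R/cli.R`, `inst/cli/dnlseg.R` — the `dnlseg` command-line tool
* `vignettes/dnlseg-methods.Rmd` — the methods vignette
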