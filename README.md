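# rdagan

Single-image ×2 super-resolution for bright-field microscopy in R, built
around a **residual dense attention generator** trained adversarially
against an image discriminator and a VGG-feature discriminator.

Microscopes trade resolution against field of view; reconstructing
high-resolution (HR) cell detail from a wide low-resolution (LR) capture is
a practical way around the trade-off. The generator here extracts shallow
features `F0`, refines them through `D = 16` residual dense attention
blocks (densely connected conv+ReLU layers, local feature fusion back to
the base width, CBAM channel-then-spatial attention, and a local residual
skip: `F_d = F_{d-1} + CBAM(F_{d,LF})`), fuses all block outputs globally
(`F_DF = F0 + F_GF`), and reconstructs the RGB image with sub-pixel
(pixel-shuffle) upsampling. Training minimizes

    Cg  = Cp + λ (Cai + Caf),        λ = 1e-3
    Cai = -log Di(Ig)                Cdi = -log Di(Ih) - log(1 - Di(Ig))
    Caf = -log Df(w(Ig))             Cdf = -log Df(w(Ih)) - log(1 - Df(w(Ig)))

alternating the image discriminator `Di` (pixels), the feature
discriminator `Df` (frozen VGG-19 `conv5_4` features `w(·)`), and the
generator per step, with ADAM (β₁ = 0.9, β₂ = 0.999) and learning rate
2×10⁻⁴ halved after epoch 200. `Cp` is pixel MSE plus VGG-feature MSE.
Evaluation is Y-channel PSNR/SSIM in BT.601 studio-swing YCbCr.

The default generator is calibrated to the method's stated parameter budget:
`D = 16, C = 7, G = 48, G0 = 64, fusion width 380` → 11,249,391 trainable
scalars = **11.25 M**.

Everything runs offline: there is no deep-learning framework dependency —
the package ships a small reverse-mode autodiff engine with
Rcpp/Armadillo convolution kernels — and a synthetic bright-field
cell-scene generator provides fixtures, so no dataset download or
pretrained weights are required (the VGG extractor defaults to a
seeded-random weight source; pretrained arrays can be plugged in).

## A worked example

```r
library(rdagan)

# 8 synthetic 64x64 bright-field patches, paired by bicubic x2 degradation
ds <- synthesize_cell_dataset(
  8, synthetic_scene_spec(side = 64, cell_count = 4,
                          radius_range = c(6, 14), seed = 101))

# the interpolation baseline on the same patches
evaluate_model(function(lr) bicubic_upsample(lr, 2), ds)
#> Metric report [dataset], 8 image(s)
#>   mean Y-PSNR: 34.04 dB
#>   mean Y-SSIM: 0.9273

# a desk-scale training run on texture-rich smoke fixtures
# (reduced generator, ~4 min on one CPU)
bench <- overfit_benchmark(seed = 101)
bench$baseline_psnr   # bicubic upsampling on the train patches
#> [1] 26.67031
bench$untrained_psnr  # randomly initialized generator: far below baseline
#> [1] 6.856457
bench$trained_psnr    # after 300 steps: above the baseline
#> [1] 28.09319

# the full calibrated architecture
gen <- build_generator(generator_spec())
param_budget_m(gen)
#> [1] 11.25

# super-resolve and inspect
sr <- sr_upscale(bench$model, ds$samples[[1]]$lr)
plot(bench$model)     # loss traces
```

The numbers mean: the untrained generator produces essentially noise
(Y-PSNR far below the baseline); 300 steps of training on the eight
patches lift it above plain bicubic interpolation, i.e. the training loop, the
gradient engine and the degradation pairing all cooperate. Full-scale training (192×192 crops, batch 16, 400 epochs,
feature discriminator on) is the same code path via `train_config()` and
`rdagan()`, but is a GPU-scale undertaking when done with the 11.25 M
default generator.

A thin CLI over the same functions lives at `inst/scripts/rdagan`
(`synth`, `degrade`, `train`, `eval`, `infer` subcommands).

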