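---
title: "Residual dense attention super-resolution: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual dense attention super-resolution: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Bright-field microscopy trades resolution against field of view: scanning a
large sample at high magnification is slow, so a common workflow captures a
wide low-resolution (LR) view and reconstructs the high-resolution (HR)
detail computationally. `rdagan` implements a single-image x2
super-resolution model for this setting: a *residual dense attention
generator* trained adversarially against two discriminators.

The generator has four parts:

1. **Shallow feature extraction.** One convolution lifts the RGB LR image
   to `G0` feature channels, `F0`. `F0` doubles as the global residual term.
2. **Residual dense attention blocks (RDABs).** `D` blocks; block `d` maps
   `F_{d-1}` to `F_d`. Inside a block, `C` convolution+ReLU layers are
   densely connected: layer `c` consumes the channel-concatenation of the
   block input and all previous layer outputs (width `G0 + (c-1) G`,
   output width `G`). *Local feature fusion* (a 1x1 convolution over block
   input plus all `C` outputs, `G0 + C G -> G0` channels) produces
   `F_{d,LF}`; a CBAM attention stage refines it; *local residual learning*
   adds the block input: `F_d = F_{d-1} + CBAM(F_{d,LF})`.
3. **Dense feature fusion.** All `D` block outputs are concatenated and
   fused by a 1x1 convolution (to the fusion width) followed by a 3x3
   convolution back to `G0` channels (*global feature fusion*), and the
   shallow features are added back (*global residual learning*):
   `F_DF = F0 + F_GF`.
4. **Upsampling reconstruction.** Per factor of 2: a 3x3 convolution
   `G0 -> 4 G0`, sub-pixel (pixel-shuffle) rearrangement, and a per-channel
   PReLU; a final 3x3 convolution maps to RGB. The SRGAN-style sub-pixel
   stage keeps all computation in LR space until the very end.

**CBAM** (convolutional block attention) is sequential channel-then-spatial
gating. Channel attention pools each channel globally by both mean and max,
sends both descriptors through a shared bottleneck MLP
(`C -> C/r -> C`, ReLU between, no biases), sums and squashes with a
sigmoid. Spatial attention reduces channels to a per-pixel mean and max
map, convolves the 2-channel stack with a single 7x7 kernel, and squashes.
Both gates lie strictly in (0, 1), so refinement never amplifies an
activation; the channel-then-spatial order is part of the contract and is
pinned by a regression test.

## Adversaries and losses

Two discriminators are trained against the generator:

* the **image discriminator** `Di` — an SRGAN-style convolutional
  classifier on pixels (eight 3x3 convolutions alternating stride 1/2,
  LeakyReLU(0.2), batch normalization from the second convolution on, dense
  head, sigmoid);
* the **feature discriminator** `Df` — a small strided classifier over
  *frozen* VGG-19 feature maps, so its judgement reflects structural
  content rather than pixel statistics. Its input comes from the VGG-19
  activation after `conv5_4` (post-ReLU, before the fifth pool), the common
  perceptual tap.

With `Ig` the generated and `Ih` the real HR batch, the losses are the
standard non-saturating forms (batch means; probabilities clamped to
`[1e-12, 1 - 1e-12]` before logs):

```
Cai = -log Di(Ig)            Cdi = -log Di(Ih) - log(1 - Di(Ig))
Caf = -log Df(w(Ig))         Cdf = -log Df(w(Ih)) - log(1 - Df(w(Ig)))
Cg  = Cp + lambda (Cai + Caf)
```

`Cp` is the perceptual loss: pixel-domain MSE plus MSE between frozen VGG
features of `Ig` and `Ih`, with both weights configurable. Training
alternates per step: `Di` on `Cdi` (generated batch detached), `Df` on
`Cdf`, then the generator on `Cg` with both discriminators frozen — the
frozenness is asserted bitwise in the test suite.

Two readings were genuinely open and are both implemented:

* **Scope of lambda.** The composite objective is typeset ambiguously in the
  method's description; since lambda is described as the weight of the GAN loss *terms*
  (plural), the default multiplies both `Cai` and `Caf`
  (`lambda_scope = "both"`); `"image_only"` preserves the alternative.
* **CBAM placement.** The attention stage is applied to the locally fused
  features *before* the residual addition (`cbam_position =
  "pre_residual"`, matching the block-internal depiction and usual
  residual-attention practice); `"post_residual"` is available.

## Architecture calibration

The reference description of the method fixes `D = 16` RDABs and the generator's
trainable-parameter budget (11.25 M), but not the per-block depth `C`, the
growth rate `G`, or the fusion/upsampling widths. We calibrated on a grid
`C in 4..8`, `G in {32, 48, 64}` with `G0 = 64`: no grid point lands inside
the two-decimal window around 11.25 M (per-block quanta are ~0.3 M), so the
hidden width of global feature fusion serves as the fine knob. The frozen
default is

```
D = 16, C = 7, G = 48, G0 = 64, fusion_width = 380  ->  11,249,391 = 11.25 M
```

counting weights and biases of every convolution, the bias-free CBAM
bottlenecks, the 7x7 spatial-attention kernels, and the per-channel PReLU.
The budget is generator-only (the comparator models it is benchmarked against are
generator-only architectures, which makes the generator-only reading the
consistent one); `count_parameters()` reports the census. A single shallow
extraction convolution is used (the description shows one; no second
pre-block convolution as in some residual-dense designs).

## Data pipeline

Training pairs are produced by **bicubic degradation** of HR images — the
same pairing the reference training protocol uses, since optically acquired HR/LR pairs
cannot be registered exactly. The bicubic dialect matters (different
toolkits differ by 0.1–0.3 dB PSNR): this package uses the Keys kernel with
`a = -0.5`, an antialias prefilter when decimating (kernel stretched by the
scale factor), and reflected borders, applied channel-wise as a separable
matrix operator. Crops are drawn at scale-aligned origins so the HR and LR
windows correspond exactly; each crop is augmented with one of the 8
dihedral symmetries.

### Synthetic scenes

To keep the whole tool testable offline, `synthesize_cell_scene()` emulates
stained bright-field cell fields: a bright background with a smooth
illumination ramp, elliptical cell bodies with darker interiors and darker
nuclei, multiplicative intra-cell texture, an eosin-like tint, Gaussian
optical blur, and additive sensor noise; everything is driven by one seed
and the cell centers are returned as provenance. The defaults
(`blur_sigma = 0.5`, `texture_amplitude = 0.2`, `noise_sigma = 0.015`,
texture correlation length ~1 px) were chosen once to read as well-focused
stained bright-field imagery: the x2 bicubic baseline on default scenes
measures ~34 dB Y-PSNR, and the scenes measurably lose edge energy under
down-up resampling (a property test pins this), so the super-resolution
task is non-degenerate. What
the generator does *not* emulate: optical point-spread functions, stage
stitching, chromatic aberration, focus drift, or the morphological
diversity of real cell types. Tests passing on these fixtures therefore
demonstrate mechanical and numerical correctness of the pipeline, not
biological image quality.

## Evaluation protocol

PSNR and SSIM are computed on the **Y channel** of the ITU-R BT.601
*studio-swing* YCbCr transform (`Y in [16/255, 235/255]`) — the convention
of the MATLAB-derived SR evaluation stack; a full-swing flag exists.
Defaults: peak 1.0; identical images report a documented 100 dB cap with a
flag rather than infinity; a border of `scale` pixels is shaved before
scoring (common SR practice; disable with `shave = 0`). SSIM uses the
standard 11x11 Gaussian window (sigma 1.5), `k1 = 0.01`, `k2 = 0.03`,
population statistics; it matches an independent reference implementation
to 1e-6 on frozen fixtures. LPIPS needs externally trained weights, so it
is a strictly optional plug-in (`lpips_fn`): reports show `NA` without it
and nothing ranks by it.

## Training schedule and state

ADAM (`beta1 = 0.9`, `beta2 = 0.999`) for all three models; learning rate
2e-4 halved once after epoch 200 (`lr_decay_every = TRUE` switches to
repeated halving for the alternative reading of the schedule). Batch size
(default 16) and total epochs (default 400) are not pinned by the source
protocol and are configurable. The update order within a step (`Di`, `Df`,
generator; one update each) is the package's reading of "alternately
minimizing". No PSNR-only pre-training phase is used by default;
`pretrain_epochs` offers one as a clearly-marked extension. Checkpoints are
versioned archives holding the spec, all parameter arrays, optimizer
moments, the config (with hash) and the RNG state; a resumed run reproduces
the unbroken run bitwise, which the suite asserts.

## Numerical choices

* Images live in `[0, 1]`; the generator output is un-clipped during
  training (losses see raw values) and clipped at inference/serialization.
* Same-padding with zero fill everywhere; spatial sizes change only in the
  pixel-shuffle stages and the discriminators' strided convolutions.
* Kaiming fan-in initialization for convolution and dense weights, zero
  biases; the residual-branch convolutions (dense layers, local and global
  feature fusion) start at a tenth of the Kaiming magnitude — the ESRGAN
  initialization for residual-dense generators — so every block is
  near-identity at step 0. This is load-bearing: with full-magnitude
  initialization, short CPU-scale runs are unstable and strongly
  seed-dependent, while the scaled scheme converges smoothly. The seed is
  recorded in the training state.
* Global max-pool ties break to the first index; probabilities are clamped
  before logarithms (the clamp perturbs a loss by at most
  `|log(eps/(eps+delta))|` near the boundary).
* The discriminator's batch normalization uses batch statistics (it is
  only ever evaluated in training mode).
* The gradient engine is a reverse-mode tape over dense arrays with
  Rcpp/Armadillo im2col convolutions; every differentiable operation is
  verified against central finite differences in the test suite.
* VGG-19 weights default to a *seeded-random* source so the package
  builds, trains and tests fully offline; pretrained arrays can be supplied
  where perceptual fidelity on real data matters. Inputs are shifted by the
  standard VGG channel means (no variance scaling).

## Desk-scale problem sizes

The suite and the reproduction script run on one CPU, so the default
experiments are scaled down: unit tests use 1–2-block generators at widths
16–32 on 8–32 px inputs; the training smoke experiment
(`overfit_benchmark()`) trains a reduced generator (1 RDAB, `C = 3`,
`G = 24`, `G0 = 32`) on 8 synthetic 64x64 HR patches for 300 steps
(batch 4, learning rate 5e-3, ADAM `beta2 = 0.99`, no augmentation) and
checks it overtakes the bicubic baseline on the train set, with the
untrained generator far below it. Two aspects of the smoke design matter:

* **Objective.** The smoke trains with the pixel (distortion) objective.
  Adversarial terms intentionally trade PSNR for perceptual texture, and
  the smoke is scored on PSNR, so the distortion objective is the correct
  instrument; the alternating adversarial loop, its freeze contracts and
  its determinism are asserted separately.
* **Fixture difficulty.** Smoke patches are synthesized at the sharp,
  texture-rich end of the scene generator's range (`blur_sigma = 0.2`,
  `texture_amplitude = 0.5`, `noise_sigma = 0.02`), where the bicubic
  baseline sits near 27 dB and super-resolution has genuine headroom. On
  the smoother package defaults, bicubic interpolation of a bicubic-
  degraded LR image is close to optimal (~34 dB) and a 300-step budget
  cannot overtake it (a 3x longer run does); that would make the check a
  statement about fixture smoothness rather than about the training
  machinery.

The full-size calibrated generator (11.25 M parameters) is built and
censused, but not trained, at test time. Training the full configuration
on real microscope corpora is a GPU-scale undertaking outside the test
surface.

## Known limitations

* No multi-GPU or mixed-precision path; the engine is single-threaded CPU
  (plus BLAS) and intended for correctness, desk-scale experiments and
  method study, not production training throughput.
* Only power-of-two scales; the reference protocol is x2.
* Batch normalization keeps no running statistics, so the image
  discriminator cannot be used as a stand-alone inference-time scorer.
* LPIPS and pretrained perceptual weights are optional plug-ins, never
  bundled.
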