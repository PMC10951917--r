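---
title: "Virtual fluorescent staining with a cross-attention conditional GAN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual fluorescent staining with a cross-attention conditional GAN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hoechst-type nuclear staining makes cell nuclei visible under fluorescence
microscopy, but the dye and the excitation light perturb live cells, and the
staining step costs time. In transmitted-light (bright-field) images the same
nuclei are nearly invisible; most of the usable signal sits in subtle,
defocus-dependent intensity patterns of the surrounding cell body and in the
faint texture of the nuclear region across a z-stack. `virtustain` learns a
mapping from a multi-slice bright-field stack to the fluorescent nuclei image
it would have produced, and at the same time labels every pixel as *healthy
nucleus*, *apoptotic nucleus* or *background*. Apoptotic nuclei matter because
programmed cell death shows up morphologically as chromatin condensation and
fragmentation (karyorrhexis): a fragmented nucleus has high internal intensity
variance in the fluorescence channel, an intact one is smooth.

## Model

### Generator

The generator is a conditional U-Net with a residual twist and two decoders:

* **Shared encoder.** Five down-sampling sub-modules. Each sub-module is
  `LeakyReLU(conv 3x3, stride 1)` followed by a `conv 4x4, stride 2`, summed
  with a `conv 1x1, stride 2` shortcut (a ResNet-style residual around the
  down-sampling step), then a LeakyReLU(0.2). A two-convolution residual
  bottleneck sits below the deepest level.
* **Two decoders.** An image decoder and a mask decoder, each with five
  up-sampling sub-modules (transposed `conv 4x4, stride 2`, concatenation of
  the same-resolution encoder output, `conv 3x3`, plus a nearest-neighbour
  upsample + `conv 1x1` shortcut, ReLU). The image head is a `conv 1x1` into
  2 channels with Tanh, so generated intensities live in [-1, 1]; channel 1
  is the healthy-nuclei image, channel 2 the apoptotic one. The mask head is
  a `conv 1x1` into 3 channels with a per-pixel SoftMax, i.e. one more
  channel than the image head, the extra channel being background
  probability.
* **Probability gating.** The returned translation is the image output
  multiplied per pixel by the matching mask probability; the background
  channel gates nothing and participates only in the mask loss. Gating means
  that a pixel the mask path considers background is forced towards zero
  intensity regardless of what the image path produced.

Channel widths double per level from `base_channels` (default 32, so
32-64-128-256-512 at the bottleneck); tests and the desk-scale runs use
`base_channels = 8`. The schedule is configurable — the doubling budget is
the standard U-Net convention and nothing downstream depends on it.

### Attention placement

Between adjacent up-sampling sub-modules there are four *intervals*; a
4-digit binary placement code says which intervals carry an attention module
(digit 1 = the deepest interval, where feature maps are smallest). Code
`"0011"` therefore puts modules at the two intervals nearest the output,
where feature maps are largest — the package default, following the general
observation that attention applied to large feature maps contributes most.

A **self-attention** module projects the C-channel feature map at N = H·W
positions into queries and keys of width `max(1, C/8)` (the usual
channels/8 reduction; the width is configurable through
`reduction_factor`) and values of width `max(1, C/2)`; the attended output
passes through a final 1x1 projection back to C channels and is added back
as `x + gamma * o(x)` with `gamma` learnable and initialized to zero. Zero
initialization makes every module an exact identity at the start of
training, which both stabilizes early optimization and gives a sharp,
testable contract.

The **cross-attention** module used between the two decoders runs two such
self-attention paths (image and mask) plus a cross term that takes its query
from the image path and key/value from the mask path, reusing those paths'
projections, with its own output projection and its own gamma. The two image
branches — the image self-attention residual and the cross residual — are
concatenated along channels and reduced by a 1x1 projection initialized to
average the two halves, so the module as a whole is also an identity at
initialization and never changes downstream shapes, whatever the placement
code. The mask path receives only its own self-attention: the mask decoder
is deliberately the simpler of the two, and the correlated term feeds the
image decoder only. Whether the cross branch should carry the residual
before concatenation was genuinely open; carrying it on both halves is what
makes the averaging-projection initialization an exact identity, which is
why that form was chosen.

### Discriminator

A conditional PatchGAN: the bright-field stack and a 2-channel fluorescent
image are concatenated along channels (so the discriminator always judges
the pair, not the image alone) and passed through `n_down = 4` of the same
residual down-sampling sub-modules, giving a 16x-reduced grid of patch
logits from a final 1-channel 3x3 convolution. Self-attention modules can be
inserted after the deeper levels (default after levels 3 and 4). Each patch
logit scores a bounded sub-window of the input; with attention disabled (or
at gamma = 0) this locality is exact, which the test suite checks by
perturbation probing.

### Spectral normalization

Every convolution weight in both networks (attention projections included)
is divided by its largest singular value, estimated by power iteration with
a persistent left vector — one iteration per training step, the standard
choice, and as many as needed (tolerance 1e-12) when a tight estimate is
requested, e.g. in tests against a full SVD. The gradient of the
normalized weight includes the rank-one `d(sigma)/dW = u v'` term. The two
output heads and the cross-attention averaging projection are exempt:
bounding the head gain would cap the mask logit confidence and the Tanh
saturation range, and the averaging projection is the identity-preserving
reference point.

## Objectives

For input stack $x$, target $y$ and generated translation $G(x)$:

* **Adversarial.** Standard conditional-GAN binary cross-entropy on patch
  logits (the pix2pix formulation); the generator uses the non-saturating
  form $-\log \sigma(D(x, G(x)))$.
* **Conventional.** $\alpha\,L_1 + (1-\alpha)\,(1-\mathrm{SSIM})$ with
  $\alpha = 0.5$; weighted by $\lambda = 100$ against the adversarial term,
  one to two orders of magnitude as in the pix2pix lineage. SSIM uses an
  11x11 Gaussian window with $\sigma = 1.5$ and constants $k_1 = 0.01$,
  $k_2 = 0.03$ on the dynamic range — the standard choices of the SSIM
  literature.
* **Mask.** Per-pixel 3-class cross-entropy between the SoftMax mask and the
  ground-truth class map, weighted by a stepped schedule
  `max(2.5, 250 * 0.9^floor(epoch/1500))`: 250 at the start so the mask
  path converges first and can feed reliable spatial information into the
  cross-attention modules, decaying 10% every 1500 epochs, never below 2.5.
  The decay is applied stepwise, once per 1500-epoch period.

Evaluation metrics are MAE, SSIM and PSNR ($10\log_{10}(L^2/\mathrm{MSE})$,
infinite at exact equality), shared between the validation loop and the
evaluation functions so the two paths cannot drift apart.

## Ground-truth preparation

The classical pipeline that turns raw fluorescent z-stacks into training
targets:

1. per-slice min-max normalization to the 8-bit range, and a per-pixel
   maximum projection along z;
2. CLAHE (clip limit 2, 8x8 tiles), then 4 passes of Gaussian smoothing
   (5x5-scale, sigma 1) so the fragments of a single apoptotic nucleus merge
   into one component, then 12 passes of 3x3 median filtering against
   salt-and-pepper noise (kernel sizes are package defaults; the pass counts
   are fixed by the procedure);
3. Otsu threshold, distance transform, local maxima as markers (minimum
   separation 7 px, peaks below 0.3 of the maximum distance discarded —
   marker parameters are package defaults, chosen at the scale of a nucleus
   radius) and marker-controlled watershed, so touching nuclei split along
   the distance-map ridge; 8-connectivity throughout;
4. per-instance standard deviation of the maximum image, split by 1-D Otsu:
   the high-variance group is fragmented, hence apoptotic. A named override
   list stands in for manual revision of borderline cases.
   With a single instance, or identical variances, everything is labeled
   healthy with a warning — the convention for early time points where
   apoptosis has not started;
5. the CLAHE-enhanced center slice masked by the healthy / apoptotic unions
   becomes the 2-channel target; instance states become the 3-class map;
   bright-field slices are min-max normalized per slice.

EBImage supplies CLAHE, Gaussian and median filtering, Otsu, the distance
transform, labeling and the seeded propagation used as the watershed flood.

## Synthetic scenes

The scene generator exists so that every stage — preparation, training,
evaluation — runs end-to-end without any real microscopy data. It
emulates, per scene and fully determined by one integer seed:

* healthy nuclei: smooth ellipses (semi-axes 9-14 px at 256x256), intensity
  around 0.55-0.7 with a gentle radial gradient — low internal variance;
* apoptotic nuclei: 3-8 bright, sharp fragments (amplitude ~0.95) inside an
  ellipse footprint over a faint base — high internal variance; fragment
  cores keep a gap of a few pixels so that the iterated Gaussian smoothing
  of the preparation pipeline genuinely has fragments to reconnect;
* occasional touching pairs (probability 0.15 that the next nucleus is
  placed adjacent), exercising the watershed split;
* bright-field stacks: 13 slices at 0.3 µm spacing, background 0.5,
  low-contrast cell-body rings larger than each nucleus (amplitude 0.08),
  a faint smooth darkening for healthy nuclei and a faint granular texture
  for apoptotic ones, slice-dependent Gaussian defocus
  (sigma = 0.4 + 1.2 µm⁻¹ · |z - focus|), additive noise (sd 0.02);
* an emulated 24-slice fluorescent z-stack (defocus blur and intensity
  fall-off away from focus) for exercising the preparation pipeline.

The nuclear signatures in bright-field are deliberately faint but present:
the premise of the method is that transmitted light carries latent
information about nuclear state, and the generator realizes that premise at
a contrast a small model can exploit. What the scenes do **not** model:
physically accurate point-spread functions, photobleaching, 3-D rendering
beyond per-slice blur, intensity statistics of any particular microscope, or
biological variability of real CHO-K1 cultures. A passing desk-scale run
therefore demonstrates that the architecture, losses and pipeline operate
and learn as specified — not that the model reaches publication-grade
accuracy on real stacks.

Datasets split 66:12:8 (train : validation : test), rounded at other sizes
with the test fold fixed;
training rotates the train/validation folds every 50 epochs without ever
touching the test fold.

## Training

Adam with betas (0.5, 0.999) for both networks. Full-scale conditions are
batch 8 and 4500 epochs; the package defaults to desk scale. Learning rates
are configurable (`lr_G`, `lr_D`); the package default keeps the
two-time-scale convention
(discriminator faster, 1e-4 / 4e-4). Augmentation applies one random
flip / 90-degree-rotation / crop jointly to stack, target and class mask —
rotations are restricted to right angles so class labels are never
interpolated. One discriminator step and one generator step per batch; the
discriminator sees the generated pair detached.

### Desk-scale study conditions

The self-contained learnability run used by the test suite: 16 scenes of
64x64 px with 3 healthy + 2 apoptotic nuclei (radii 5-8 px), placement
"0011", `base_channels = 8`, 30 epochs at batch 1 with `lr_G = 2e-3`,
`lr_D = 2e-4`. At this horizon (about 400 optimizer steps) the larger
generator rate lets the heavily weighted mask objective shape the shared
encoder quickly, while the slower spectrally normalized discriminator
provides an adversarial signal without overwhelming it; with the package's
full-scale default rates the 30-epoch horizon is simply too short for the
mask path to leave the all-background solution. Held-out evaluation uses
the validation and test folds, neither of which enters training within 30
epochs (the first fold rotation would occur at epoch 50). The same
conditions, with the mask decoder removed and two output channels
(`variant = "single_2ch"`), probe the known failure mode of mask-free
multi-channel translation: the per-channel output energy is reported to
show whether generation collapses toward one channel.

## Numerical choices and conventions

* Arrays are (H, W, C); pixels are 0-based only in file formats, 1-based in
  R. Class labels: 0 background, 1 healthy, 2 apoptotic; mask channels are
  ordered healthy, apoptotic, background.
* SSIM statistics are computed on the valid interior (no padding), window
  clamped to the image size; a uniform full-image window reproduces global
  mean/variance statistics exactly, which the tests use as an oracle.
* The SoftMax implementations subtract row maxima; cross-entropy is fused
  with the SoftMax for stability and probabilities are floored at 1e-12
  when log-transformed.
* Power iteration: persistent vector, one step per training forward;
  convergence-stopped (1e-12) when several steps are requested. An all-zero
  weight is returned unchanged with a warning, since its spectral norm is
  undefined.
* Detection scoring matches each truth instance to the predicted component
  of maximal overlap and accepts it at intersection-over-truth >= 0.3 — a
  deliberately tolerant threshold, since translated nuclei of difficult
  (e.g. necrosis-like) cells are systematically smaller than the truth.
  False positives are normalized by the number of predicted components, the
  remaining rates by the number of truth instances; all raw counts are
  returned so any alternative normalization can be recomputed.
* The translation is clamped to [0, 1] before computing image metrics
  against targets stored in [0, 1]; the Tanh range [-1, 1] is retained
  inside the network.

## Limitations

* The networks run on a package-internal autodiff engine: single-threaded
  CPU, dense attention with O(N²) memory in the number of spatial positions.
  It is built for correctness and desk-scale experiments, not for training
  at 512x512 and 4500 epochs.
* Cross-validation rotates folds cyclically rather than sampling balanced
  folds; with very small datasets a rotation can leave few training scenes.
* Manual curation steps of ground-truth preparation (early-time-point
  filtering, visual revision of the variance split) are represented by an
  override interface, not automated heuristics.
* The necrotic (karyolysis) case — nuclei faint in both modalities — is not
  represented in the synthetic scenes; no quantitative claims are made or
  tested for it.
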