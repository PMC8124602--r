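---
title: "Methods: depth-image pig weight and body-size estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-image pig weight and body-size estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

A depth camera looks straight down at a weighing platform from 1650 mm.
Each acquired frame is a single-channel image whose pixel value is the
camera-to-surface distance in millimetres, so the pig back appears as a
height field above the platform. Six continuous traits are regressed from
one frame: body weight (BW, kg), shoulder width (SW), shoulder height
(SH), hip width (HW), hip height (HH) and body length (BL, all cm). BL is
the ear-root to tail-root distance; SW and HW are the widest transverse
extents at shoulder and hip; SH and HH are the highest points of the
shoulder and hip sections.

The estimator is a *multiple-output regression CNN*: a classification
backbone with its classifier removed, global average pooling retained, and
six parallel single-node dense layers with no activation attached to the
pooled features. Head `i` is trained against label `i`; the loss is the
unweighted sum of the six per-target mean squared errors.

## The synthetic scene generator

The farm datasets behind the original system are not public, so the
package generates its own scenes with analytically known ground truth.
A green test on this generator establishes *parameter recovery under the
stated world*, not farm-level accuracy.

### Body geometry

The pig body is a loft of half-elliptical cross-sections along the spine.
Half-width `w(s)` and apex height `a(s)` are piecewise linear through six
stations: snout tip, ear root, shoulder (at 0.20 BL), hip (at 0.85 BL),
tail root and tail tip. Head and tail are tapered appendages beyond the
BL extent (0.15 BL and 0.05 BL long), so BL keeps its ear-root-to-tail-root
meaning and nothing ever needs to "remove" head or tail from an image.
The section area is `(π/2) w(s) a(s)`; with piecewise-linear profiles the
area is quadratic per segment, so per-segment Simpson integration gives
the *exact* enclosed volume. This closed form is the oracle that the
renderer is tested against (2 % at the default 720 × 1280 resolution,
0.5 % at 4×).

Posture enters as: yaw (spine direction vs. platform axis), lateral
offset, head pitch (a ±4 cm vertical displacement of the shoulder apex —
the magnitude observed when a drinking pig moves its head), and spine bend
(a parabolic lateral arc parameterised by the angle between front and rear
spine directions). Yaw and offset are truncated so the body stays on the
1.5 m × 0.5 m platform; the renderer refuses bodies that overhang it.

### Population sampling

`sample_phenotype()` draws BW uniformly over the population range
(16.5–117.0 kg by default), a lognormal weight-noise factor
(`weight_noise_sd = 0.03`), and per-trait lognormal shape multipliers
(`shape_noise_sd = 0.02`, truncated at ±5 %), then solves for the latent
size scalar such that

```
BW = density × volume(phenotype) × noise
```

holds exactly, with `density = 1.0 g/cm³`. Because every linear trait
scales with the latent size, volume — and noise-free weight — scales with
its cube. Drawing BW first keeps the weights exactly uniform in range
(mean = midpoint, which the Monte-Carlo test checks against its closed
form) and makes the weight law hold without rejection sampling.

Choices worth noting:

- *Density 1.0 and the base proportions* (BL 100, SW 26, SH 56, HW 24,
  HH 54 cm at latent size 1) produce slightly compact pigs — a 117 kg
  animal has BL ≈ 114 cm, a little shorter than typical finishing pigs —
  because the loft is "fuller" than a real torso. Any smooth monotone
  weight–shape law suffices for recovery testing, so this is accepted and
  not tuned.
- *SH label semantics.* The camera sees the shoulder apex displaced by
  head pitch. By default labels use the **as-imaged** apex
  (`sh_label = "as_imaged"`), making the learning task self-consistent;
  `"at_rest"` reproduces the irreducible SH error structure of real data,
  where the measured standing height differs from what the image shows by
  up to ±4 cm.
- *Sensor model.* Gaussian depth noise (sd 2 mm, a typical stereo-depth
  figure at this range) is added last, clipped to `[0, 1650]` and
  quantised to integer millimetres, matching 16-bit PNG storage.
- *Limit bars.* The crate's side rails can be rendered
  (`include_limit_bars = TRUE`) as 700 mm rails along the platform edges;
  they are off by default so that background-conservation invariants stay
  exact.

What the generator does **not** emulate: legs and ears (inside the loft
silhouette), occlusion by rails, multi-pig scenes, depth shadows or
material-dependent dropout, and the correlation structure of repeated
images of the same animal. Synthetic results therefore say nothing about
farm-level MAE; they establish that the pipeline is implemented correctly
and can recover known parameters.

## Preprocessing

`P_i = camera_distance − P_o` (an involution; pixels above the camera are
clipped to height 0 with a warning count), then a linear map of
`[0, camera_distance]` to 0–255, then a bilinear square resize.

Numerical conventions the sources leave open, fixed here once:

- **Rounding**: round half up on the gray scaling, so 825 mm → 127.5 →
  128.
- **Resize kernel**: bilinear with half-pixel centre alignment; chosen as
  the common default and because it preserves the mean (the checkerboard
  test) and the pig's relative position (the centroid test, within one
  rescaled pixel). Aspect ratio is *not* preserved: 1280 × 720 is
  squashed to the square input, as implied by the absence of any padding
  step.
- **Input normalisation**: the model input stage maps 0–255 to [−1, 1]
  (`x / 127.5 − 1`), configurable per spec of the model
  (`model_spec(input_scale =, input_offset =)`).
- Channel replication (gray → 3 channels) happens inside the model input
  stage, not in preprocessing, keeping preprocessing output single-channel.

## Model factory and parameter counting

The four named backbones follow their published definitions layer by
layer: dense blocks with growth 32 and half-compression transitions;
pre-activation bottleneck residual stacks (3/8/36/3 blocks); the
depthwise-separable entry/middle/exit flows; and inverted residual
bottlenecks with expansion 6. Input is 3-channel (the gray image
replicated), which both matches pretrained-weight shapes and is required
to reproduce the published parameter totals, whose first convolution
assumes 3 input channels.

Counting conventions: every weight, bias and batch-normalisation
statistic counts toward the total; *trainable* excludes only the
batch-normalisation moving means and variances (2 per channel). Under
this convention the package reproduces all eight published totals exactly
(`test-acceptance.R`, criterion 1). A literal reading of the source
description — excluding *all* batch-normalisation parameters — does not
reproduce the printed numbers; the moving-statistics convention does, so
it is taken as what was meant.

`tinycnn` is this package's own desk-scale backbone: four 3 × 3 stride-2
convolutions (16, 32, 64, 256 channels, bias, ReLU, no batch norm) and
global average pooling. The final width of 256 is deliberate: with Adam's
per-step displacement bounded by the learning rate (0.001), a six-head
linear readout over F pooled features can move its output by roughly
`F × lr` per step; F = 256 lets the heads reach the label scale (up to
~120) within the 30-epoch training budget of the scaled-down recovery
test, whereas F = 64 cannot.

## Training

- **Loss**: the summed per-target MSE, in mixed units (kg² + cm²),
  exactly as defined — no per-target weighting or standardisation.
- **"150 iterations"** is read as 150 *epochs* (the loss histories reach
  ~150 on their x-axis and convergence is described at "the 80th
  iteration"); configurable via `train_config(epochs =)`.
- **Adam** uses the published defaults beyond the stated learning rate:
  β₁ = 0.9, β₂ = 0.999, ε = 1e−7.
- **Split**: shuffled 7:3 with `round(ratio × n)` training samples —
  38,112 modelling images split 26,678 / 11,434.
- **Checkpointing**: the full validation set is evaluated after every
  epoch; the parameters of the best epoch are retained; no early
  stopping. Re-evaluating the retained parameters reproduces the stored
  best loss to 1e−6 relative.
- **Gradient support** covers sequential conv/ReLU/GAP graphs — i.e.
  `tinycnn`. The branched backbones are forward-only on CPU: training a
  58 M-parameter network in interpreted R would be pointless, and every
  desk-scale criterion trains `tinycnn` only. `train()` fails fast with
  that explanation for branched graphs.

Degenerate inputs: non-finite loss aborts with the epoch index; empty or
single-sample data are rejected at the split.

## Evaluation

RMSE and MAE use the standard formulas; **MRE** divides by the *measured*
value (the usual "relative error vs. ground truth" reading — the source
prints only the name, not the formula) and is reported in percent. R² is
`1 − SS_res/SS_tot` about the measured mean and is undefined (error) for
constant measured vectors. The aggregate "total MSE" is the sum of
squared per-target RMSEs, reported in the same mixed kg²-labelled units as
the training loss. Mean estimation time is wall-clock per image and is
report-only — never asserted, never part of acceptance.

## Capture trigger

`should_capture()` is the literal rule: all `window = 4` readings inside
the closed population interval *and* spread strictly below 0.2 kg.
The stream scanner adds one piece of behaviour the hardware description
leaves open: a refractory cooldown (default = window size) after each
capture, so one stable plateau does not fire on every subsequent window.
With the cooldown set to 0 every qualifying window fires, which is the
mode the brute-force equivalence test exercises most heavily.

## Known limitations

- The renderer's half-elliptical loft makes width traits (SW, HW) visible
  as silhouette extent and height traits as gray level; real pig backs
  have flatter, asymmetric sections.
- The CNN engine is CPU-only and single-threaded apart from BLAS; the
  large backbones are practical for parameter counting and single
  forward passes, not training.
- PNG support is a minimal grayscale codec (bit depths 8/16, colour type
  0, filters 0–4 on read) — sufficient for the depth-image contract, not
  a general PNG library.
- The 2-D colour companion images of the original acquisition system are
  out of scope entirely.
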