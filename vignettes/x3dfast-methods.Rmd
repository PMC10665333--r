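---
title: "Two-pathway spatiotemporal recognition of dairy cow behavior: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pathway spatiotemporal recognition of dairy cow behavior: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the shipped experiments do and do
not demonstrate.

## The recognition problem

Barn-camera monitoring of dairy cows asks for clip-level classification of
four behaviors: standing, lying, walking, and mounting (an estrus indicator in
which one cow overlaps another). Two of these classes are essentially *static*
— a single well-chosen frame separates standing from lying by body pose — and
two are essentially *dynamic*: walking is a translation over time, and
mounting is a characteristic two-body configuration that forms and dissolves.
A recognizer therefore needs detailed spatial features *and* higher-rate
temporal features, which is what the two-pathway architecture provides.

## The model

`x3dfast()` fits a two-pathway 3D convolutional network (the X3DFast
architecture) assembled from four components:

**X3D pathway** (spatial emphasis). A stem convolution followed by four
stages of 3, 5, 11 and 7 residual convolution groups (26 in all) over a
low-rate clip (8 frames in the full profile). Each group's residual branch is
a depthwise-separable 3D convolution — a per-channel `3x3x3` convolution plus
a `1x1x1` pointwise mix — which cuts the branch's weight count from
`C_in*C_out*27` to `C_in*27 + C_in*C_out`. To compensate for the lost
capacity, an *action attention* block follows every group.

**Action attention.** Three excitation branches, each producing a sigmoid
mask and returning `Y = X + X * Mask`:

* *STE* (spatial–temporal): the channel-mean volume passes through a single
  `3x3x3` convolution, giving a `(N,T,1,H,W)` mask over frames and positions.
* *CE* (channel): global spatial pooling to `(N,T,C,1,1)`, a squeeze to
  `ceil(C/r)` channels, a kernel-3 convolution along the frame axis, and an
  expansion back to `C`.
* *ME* (motion): after the same channel squeeze, each frame `t+1` is passed
  through a `3x3` spatial convolution and the frame `t` representation is
  subtracted; the frame-length is restored with a zero in the *last* temporal
  slot, then spatial pooling, expansion and the sigmoid follow.

The compression ratio is `r = 16` throughout, and the branch outputs are
combined by an elementwise mean: the combination rule was an open choice, and
the mean preserves the activation scale where a sum would triple it (a sum
remains available via `action_config(combine = "sum")`).

**Fast pathway** (temporal emphasis). The same stage layout at an
`alpha`-times higher frame rate and `beta`-scaled channel widths; the
residual cores are R(2+1)D factorizations: a `1xdxd` spatial convolution into
`M` mid-channels, a rectifier, then a `tx1x1` temporal convolution. `M` is
chosen by `solve_mid_channels()` as the largest integer for which the
factorized pair does not exceed the full `txdxd` kernel's weight count,

```
M = floor( t d^2 N_in N_out / (d^2 N_in + t N_out) ),
```

clamped to at least 1 so degenerate single-channel test configurations remain
buildable. At `(t,d,N_in,N_out) = (3,3,64,64)` this gives `M = 144` and both
factorizations count exactly 110 592 weights. The factorization doubles the
nonlinearities per unit at matched parameter count.

**Lateral connections.** After every stage, the fast pathway's features are
passed through a time-strided 3D convolution (kernel `(5,1,1)`, stride
`(alpha,1,1)`, padding `(2,0,0)`) so the frame counts match, reweighted by a
3D squeeze-excitation gate (ratio 16), and concatenated onto the X3D
pathway's channels (X3D channels first, preserved bitwise). Fusion is
directional — fast into X3D — and feeds the next X3D stage.

**Predictor.** Global average pooling of the final fused volume and of the
fast pathway's final features, concatenated, then a two-layer head (hidden
width 256 in the full profile, rectifier, dropout 0.5, 4-way output).
Training minimizes the mean cross-entropy
`L = -(1/N) sum_i sum_c y_ic log p_ic` with probabilities clamped at `1e-12`;
accuracy is top-1 with ties broken deterministically toward the lowest class
index.

### Values the architecture's description leaves open

Several constants are not derivable from the architecture's published
description and were fixed once, as package defaults, all configurable in the
YAML profile:

* stage widths 24/48/96/192 (X3D lineage), stem width 24;
* pathway ratios `alpha = 4`, `beta = 1/8` (canonical two-pathway ratios);
* lateral kernel/stride/padding as above, `out_channels = 2 * C_fast`;
* "same" padding everywhere, so stride-1 blocks preserve extents; spatial
  downsampling (stride 2) at stages 2–4 only, never temporal;
* convolution biases off wherever normalization follows; per-channel
  batch-style normalization after each convolution, rectifier nonlinearity;
* the residual branch's final normalization scale initializes at zero, so a
  fresh group is an exact identity and optimization starts from the shortcut
  chain. There is no activation after the residual addition.

One printed formula required a decision: the published closed form for the
R(2+1)D mid-channels (difference in the numerator) contradicts the
parameter-equality constraint it is said to solve; this package solves the
constraint itself (product in the numerator, floored), which reproduces the
matched counts verified in the tests.

## Training protocol

The protocol follows the architecture's published recipe where stated: plain
SGD, learning rate 0.01, training from scratch, no schedule; clips resized so
the short side is 256 and cropped to 224 at full scale. Unstated extras
default conservatively: momentum 0.9 (configurable to 0), no weight decay,
batch size 8 (tiny) / 32 (full), center crop at evaluation time,
normalization constants (0.45, 0.225) recorded in every checkpoint. The
`tiny` training scale (30 epochs, 32-px inputs) sizes the desk experiments.

## The synthetic clip simulator

The farm video dataset behind the architecture is not redistributable, so the
package ships a simulator that reproduces the *statistical structure* the
recognizer exploits, not the imagery:

* four classes in the realistic barn mix 1799 : 1947 : 1130 : 774
  (standing : lying : walking : mounting), with class-specific durations
  (standing/lying 1–2 s, walking 1–3 s, mounting 2–4 s) at 12.5 fps on a
  64x64 canvas by default;
* bodies are textured ellipses on a textured background: standing/walking
  upright (aspect 13/6), lying flat (6/14) — the aspect contrast above 1.5x
  guarantees spatial separability; walking translates at 2 px/frame with a
  vertical bob and bounces off the canvas edges (at least twice the 1 px
  static jitter, guaranteeing temporal separability); mounting renders two
  bodies on a 12-frame mount/apart cycle that keeps them overlapping in at
  least half the frames of any clip length;
* degradations applied in a fixed order — illumination gain, Gaussian blur,
  occluder rectangles — emulate the barn conditions; labels are unchanged and
  the stored foreground masks are clipped by occluders;
* everything is a pure function of the seed: identical seeds give
  byte-identical datasets.

A rule-based kinematic oracle (`oracle_classify()`: Otsu segmentation,
connected components, centroid displacement, bounding-box aspect) serves as
the generator's acceptance gate: it must recover at least 95% of clean-clip
labels, which certifies that the class signal exists independently of any
learned model. A single-frame variant shows the complementary property: the
spatial-only view separates standing from lying but cannot assert walking at
all — motion is genuinely temporal in these data. Oracle thresholds (minimum
component 40 px, two-body area 420 px, displacement 6 px, aspect 1.15) match
the default geometry at a 64x64 canvas and scale with it.

What passing these experiments does *not* show: robustness to real barn
imagery — deformable animals, perspective, herd occlusion, night footage —
is out of reach of textured ellipses. The simulator validates the
architecture's mechanics (spatial vs temporal discrimination, fusion,
attention), not field performance.

## Desk-scale experiment sizes

The shipped experiments use the `tiny` profile (stages 1/1/2/1, widths
8/12/16/24, 4/8 frames, `alpha = 2`, `beta = 1/2`, hidden width 64) on 32-px
inputs:

* *overfit gate*: 16 clips (4 per class), at most 200 optimizer steps, must
  reach training top-1 of 1.0;
* *generalization gate*: 280 clips split 200/80 by a stratified 5/7 split,
  12 epochs (validation top-1 crosses 0.99 around epoch 5 under the default
  conditions; the `train_config()` default remains 30 epochs), must reach
  validation top-1 of at least 0.90;
* *localization*: gradient-weighted class activation maps on 20 fresh
  walking clips from the generalization model.

## Class activation maps

`compute_cam()` implements gradient-weighted mapping: the target-class logit
is backpropagated to a fused feature volume; with the default `"gradcam"`
method the channel weights are the pooled gradients and the heatmap is the
rectified weighted channel sum; the `"elementwise"` method instead sums the
rectified gradient-activation product over channels. Per-frame maxima are
normalized to 1.

Two resolution realities drive the localization experiment's design, decided
from the receptive-field analysis before the experiment was frozen:

* at 32-px inputs the final fused volume is 2x2 — too coarse to localize — so
  the experiment maps the stage-2 fused volume (8x8, stride 4), using the
  `stage` argument; the elementwise method localizes markedly better on such
  coarse grids;
* the evaluation dilates the per-frame foreground mask by 13 px: one temporal
  sampling step of walking motion (2 px/frame over ~6 source frames between
  mapped frames, i.e. the displacement the temporal receptive field smears
  over) plus the stage-2 feature stride. The dilated mask covers roughly half
  the canvas, so the 70% gate sits well above the ~48% chance level of a
  random peak. The shipped pinned-seed experiment scores about 79%;
  across training seeds the rate varies roughly between 65% and 85%.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clamped at `1e-12`; probability rows must
  sum to 1 within `1e-6` and labels must be one-hot.
* Excitation masks and SE gates are clamped to `[1e-12, 1 - 1e-12]` after
  the sigmoid so the open-interval (0,1) contract survives double-precision
  saturation at extreme activation scales.
* Batch normalization uses `eps = 1e-5`, running-statistic momentum 0.1;
  evaluation mode uses running statistics and is bitwise deterministic.
* The motion branch refuses single-frame input (`T = 1`) with an error that
  tells the caller to bypass it; channel squeezes clamp to at least one
  channel; `solve_mid_channels()` clamps to 1.
* Clips shorter than the fast pathway's frame count are looped (wrap
  padding) before uniform index sampling; uniform indices are strictly
  increasing and clamped to the clip length.
* Argmax ties (`top1()`, `predict()`) resolve to the lowest class index.
* The stratified split takes `floor(frac * n_class)` per class, remainder to
  validation.

## Known limitations

* The automatic-differentiation engine is purpose-built for this
  architecture's operation set; it is single-threaded R plus compiled
  convolution kernels and is sized for desk-scale experiments, not for the
  256-epoch full-resolution protocol.
* Fusion is concatenation-only and directional (fast into X3D), matching the
  architecture; summation-style or bidirectional fusion is out of scope.
* The simulator does not model photorealism, multi-animal scenes beyond the
  mounting pair (distractor bodies are static), or night-vision imagery.
* Checkpoints are R serializations of configuration plus parameter state;
  there is no export to external inference runtimes.
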