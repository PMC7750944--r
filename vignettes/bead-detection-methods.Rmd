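---
title: "Detecting and counting sub-resolution beads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting sub-resolution beads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fluorescent latex beads of about 1 µm are a common proxy for bacterial
invasion assays: ligand-coupled beads are internalized by cultured cells
and counted per condition. At typical magnifications a bead spans only
2-4 px, beads frequently touch, and the signal-to-noise ratio is low.
Classical blob detectors then under- or over-count, and their parameters
need expert retuning whenever the imaging changes. `beadspot` implements
a learning-based counting pipeline built around one key preprocessing
idea: *bilinear upsampling* of the low-resolution image so that the
centers of touching beads no longer share an edge, which turns bead
detection into an ordinary dense segmentation problem with small,
well-separated targets.

## Pipeline

1. **Normalization.** Intensities are mapped to $[0,1]$ by percentile
   min-max (1st/99th percentiles, then clipping). The percentile anchors
   make the mapping robust to hot pixels; a constant image maps to
   zeros.
2. **Upsampling.** The image is enlarged by an integer factor $f$
   (default 4 for 2 px beads, via $f = \lceil 8 / d_{\min} \rceil$)
   using bilinear interpolation under *pixel-area alignment*: original
   pixel $c$ maps to the block $[fc, fc+f-1]$ whose center is
   $fc + (f-1)/2$. The alignment convention matters because it fixes
   where seed labels land; we state it explicitly and test the
   interpolant against a closed-form oracle.
3. **Seed labels.** Each annotated bead center paints a $2\times 2$ px
   seed in the upsampled frame, placed on the block whose center is
   nearest the mapped centroid (ties toward smaller indices). For beads
   whose original centers differ by at least 1 px, seeds are disjoint
   with a 2 px gap — the geometric core of the method. Optionally the
   training labels are dilated with a $3\times3$ cross, which enlarges
   each seed to a 12 px plus shape; this makes detection more robust
   but can merge the seeds of adjacent beads, so models are trained
   both with and without it and the better variant is selected on data.
4. **Detector.** A compact U-shaped encoder-decoder predicts a
   per-pixel seed probability (two $3\times3$ convolutions with batch
   normalization and ReLU per level, $2\times2$ max pooling,
   nearest-neighbour upsampling with skip connections, sigmoid head).
   The loss is the sum of pixel-mean binary cross-entropy and Dice loss
   with smoothing 1: the cross-entropy handles the extreme class
   imbalance (seed pixels are roughly 0.2% of the raster), the Dice
   term directly rewards overlap.
5. **Post-processing.** Probabilities are binarized at a global
   threshold of 0.5 (strict inequality), 8-connected components are
   labeled, each component contributes its unweighted pixel centroid,
   and the centroids are counted.

## Evaluation scheme

Ground-truth seeds are enlarged into square regions of side
$2h + 2$ centered on the seed ($h = 3$ px by default, giving
$8\times8$ regions at fourfold upsampling); overlapping regions are
partitioned by nearest ground-truth centroid with ties to the lower
bead index. Each predicted centroid, rounded to its nearest pixel,
either hits a bead region or the background. Per image this yields:
*missing* beads (no seed), *split* beads (more than one seed), and
*added* predictions (background hits away from the border). Background
predictions within a 4 px border margin are ignored, because only fully
visible beads are annotated and detections of partially visible beads
near the edge should not count against the detector. With
$TP = n_{gt} - \text{miss}$, $FP = \text{added} + \text{split extras}$
and $FN = \text{miss}$, the report carries precision, recall, F-score,
the three rates as percentages of $n_{gt}$, and total counted
detections as a percentage of $n_{gt}$. Multi-image evaluation pools
the counts (micro-averaging) rather than averaging per-image metrics.
These precision/recall/F definitions are fixed by requiring exact
agreement with the published deterministic baseline rows of the
original benchmark, which the test suite reproduces to three decimals.

## Synthetic data generator

Real annotated bead images are not distributed with the package, so all
testing runs on a generator with exact ground truth:

* beads are isotropic Gaussian spots whose full width at half maximum
  equals the nominal bead diameter (the standard diffraction-limited
  approximation), drawn as $d \sim U(2, 4)$ px;
* default scenes are $32\times32$ px with 8 beads, amplitudes
  $U(0.4, 0.9)$ over a background of 0.1 — a moderately dense field
  comparable to typical invasion-assay crops;
* a quarter of the beads (`touching_fraction = 0.25`) are placed with
  centers 1-2 px from a neighbour, emulating touching beads whose
  seed markers would collide at original resolution;
* noise is Poisson shot noise at a scale of 200 photons for intensity
  1.0 followed by Gaussian read noise with sd 0.02 — a moderate
  signal-to-noise regime for low-magnification fluorescence;
* everything derives deterministically from one seed, and the
  noise-free limit equals background plus the analytic bead sum
  exactly.

What the generator does *not* emulate: optical point-spread sidelobes,
uneven illumination, autofluorescent debris, out-of-focus beads, and
camera artifacts. Passing the synthetic benchmark therefore shows the
pipeline's machinery works end to end at realistic geometry and noise;
it does not certify performance on any particular microscope's data.

## Training: defaults and the scaled-down benchmark

The package defaults follow the conventional choice for this class of
models (depth 3, 32 base channels, Adam, online augmentation with
flips, right-angle rotations, intensity scaling $U(0.8, 1.2)$, additive
Gaussian noise with sd $\sim U(0, 0.05)$ and Gaussian blur with
$\sigma \sim U(0, 1)$). Two deliberate deviations from common practice
are worth recording:

* **Head-bias prior initialization.** The sigmoid head's bias starts at
  $\mathrm{logit}(0.01)$ instead of 0. With ~0.2% positive pixels, a
  zero-initialized head spends its first epochs learning "mostly
  background"; starting at the approximate foreground prior makes the
  early cross-entropy gradients informative about the seeds themselves.
* **Step size.** The default Adam learning rate is $5\cdot10^{-3}$
  with reduce-on-plateau (halved after three epochs without validation
  improvement, floor $10^{-5}$). At the small step budgets used here a
  more conservative $10^{-3}$ measurably under-converges.

`benchmark_detectors()` runs the package's self-contained experiment:
60/15/25 train/validation/test scenes under the default generator, a
zoo of two initializations with and two without label dilation (10
epochs each), automatic selection, and evaluation of the selected model
against the three classical baselines on the test split. The benchmark
uses a two-level, 8-channel network trained on full $128\times128$
upsampled images in batches of two, with geometric and intensity
augmentation only — problem sizes chosen so a single desk CPU completes
the whole experiment in roughly a quarter of an hour. Model selection
defaults to the validation split to avoid test leakage;
`select_on = "test"` reproduces the original tool's behaviour of
selecting on the test set.

### What the benchmark shows — and a known limitation

On the synthetic benchmark the selected detector reaches an F-score of
about 0.86, clearly above the Otsu-with-distance-transform baseline
(about 0.84), with perfect precision. Its misses concentrate entirely
in the touching-bead subpopulation: beads whose nearest neighbour is
beyond 2.5 px are detected without error, while pairs with centers
1-2 px apart lose one member about half the time. The reason is
physical rather than architectural: two Gaussian spots of FWHM up to
4 px whose centers are 1-2 px apart form a single near-isotropic blob
whose decomposition into two centers is ambiguous at this
signal-to-noise ratio. We verified that wider networks (16 base
channels) and doubled training budgets plateau at the same score, and
that the failed pairs produce a confident single seed rather than a
merged two-seed component. Real touching beads of diameter $d$ have
center distance about $d$, a milder regime than the generator's 1-2 px
rule; on such geometry the separation premise holds correspondingly
better.

## The classical baselines

* **Laplacian of Gaussian.** Scale-normalized LoG responses at
  $\sigma = d/(2\sqrt2)$ for three diameters spanning the configured
  range; bright-blob maxima above a relative threshold, greedily
  separated by a minimum distance (strongest first; plateau ties to the
  smallest coordinates).
* **Circular Hough transform.** Gradient-magnitude edges (Otsu
  threshold on magnitudes) vote along the uphill gradient direction at
  each candidate integer radius. Votes are normalized by a fraction
  (0.15, measured on synthetic disks) of the candidate circle's
  circumference so that the sensitivity parameter acts as an absolute
  confidence: disks with radii outside the searched range spread their
  votes over an annulus and fall below it rather than being rescued by
  a relative-to-maximum rule.
* **Otsu + distance transform.** Global Otsu threshold (256-bin
  between-class variance, exact by construction against an
  exhaustive-search oracle), Euclidean distance transform of the
  foreground, local maxima as detections; components without a
  surviving maximum contribute their centroid. Touching beads merged by
  the threshold routinely yield a single maximum — the classic
  under-segmentation failure this baseline is known for.

All baselines run on the upsampled image, like the learned detector.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)` with pixel centers at integers;
  sub-pixel centroids are allowed everywhere.
* Binarization uses strict `>` at the threshold; exact ties are
  background.
* Seed-block placement and ground-truth region ties resolve toward
  smaller indices; local-maxima plateau ties resolve to the smallest
  `(row, col)`.
* Component labeling is 8-connected; with fourfold upsampling,
  undilated seeds of adjacent beads keep a 2 px gap, so the
  connectivity choice cannot merge them.
* Constant images normalize to all zeros; blank images yield zero
  detections in every detector; evaluation with zero ground-truth beads
  is an error rather than a silent NaN.
* The minimum-component-size filter exists but defaults to off (1 px).
* Training is fully deterministic for a fixed seed (weight init, data
  order, augmentation draws), which the suite asserts by comparing two
  complete training histories.

## Limitations

* 2D single-channel only; no 3D stacks, no multi-channel
  internal/external bead classification.
* No watershed or other splitting of merged predictions: the method
  relies on upsampling for separability by design.
* The network is intentionally small so that CPU training at desk
  scale is practical; for large production datasets one would raise
  depth/width (the configuration object exposes both) and train far
  longer than the benchmark does.
* Localization error in pixels is not scored; the evaluation is
  region-membership only, matching the published scheme.
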