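# beadspot

Detection and counting of sub-resolution fluorescent beads in
low-resolution microscopy images.

## The problem

Ligand-coupled fluorescent latex beads (~1 µm) are used to mimic
bacterial invasion of cultured cells; quantifying an experiment means
counting beads that appear only 2–4 px wide, frequently touch each
other, and sit on noisy backgrounds. Classical detectors (Laplacian of
Gaussian, circular Hough, Otsu thresholding) under- or over-count in
this regime and need expert parameter tuning. `beadspot` implements a
learning-based pipeline for biologists' bead-counting workflows and for
method benchmarking.

## The method

The core idea is a *bilinear upsampling* preprocessing: enlarging the
image fourfold (for 2 px beads, via `factor = ceiling(8/min_diameter)`)
so that the centers of touching beads no longer share an edge. Each
bead center is then represented by a 2×2 px *seed* in the upsampled
frame, and a compact U-Net is trained to predict seed probabilities
with the compound loss

    L = BCE(p, t) + 1 − (2·Σ p·t + 1) / (Σ p + Σ t + 1)

(pixel-mean binary cross-entropy plus smoothed Dice loss). Predictions
are binarized at 0.5, 8-connected components are reduced to centroids,
and centroids are counted. Several models are trained with and without
a cross-shaped dilation of the training labels, and the best one is
selected automatically.

Detection quality is scored by enlarging ground-truth seeds into 8×8
regions and counting **missing** beads (no predicted seed in the
region), **split** beads (several seeds), and **added** predictions
(seeds in the background, excluding a border margin), from which
precision Q_P, recall Q_R, F-score Q_F and a total detections
percentage are derived.

The package also ships the three classical baselines, a synthetic
bead-scene generator with exact ground truth (Gaussian spots, Poisson
shot noise, Gaussian read noise, touching-bead placement), and a CLI.

## Worked example

Generate a synthetic scene, run the Otsu+EDT baseline on the upsampled
image, and score it against the exact ground truth:

```r
library(beadspot)

scene <- generate_scene(scene_config(rng_seed = 42))
up    <- upsample_bilinear(normalize_intensity(scene$image), 4)
det   <- detect_otsu_edt(up, baseline_params(diameter_range = c(8, 16)))
count_beads(det)
#> [1] 6

gt_up   <- map_centroid_up(scene$annotation[, c("row", "col")], 4)
regions <- enlarge_gt(gt_up, dim(up))
compute_metrics(match_detections(regions, det))
#> bead detection report (n_gt = 8)
#>   F-score  Q_F     0.857
#>   precision Q_P    1.000
#>   recall    Q_R    0.750
#>   split     %      0.00
#>   missing   %      25.00
#>   added     %      0.00
#>   detections %     75.00
```

The scene contains 8 beads; the baseline finds 6 of them (the two
members of touching pairs merge under thresholding), giving recall
0.75 at perfect precision — the characteristic under-segmentation the
learned detector is designed to beat.

The full self-contained experiment — generate 60/15/25 scenes, train a
2+2 model zoo (with/without label dilation), auto-select, and compare
against all three baselines — is one call (about 15 minutes on one
CPU):

```r
res <- benchmark_detectors(master_seed = 11)
sapply(res$reports, `[[`, "Q_F")
```

From the shell, the same building blocks are available as subcommands:

```sh
inst/scripts/beadspot generate --out data --seed 1
inst/scripts/beadspot train    --data data --out run --epochs 10
inst/scripts/beadspot bench    --data data --out run --method otsu
inst/scripts/beadspot evaluate --data data --model run/model --out run
```

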