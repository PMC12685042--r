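# lfcalcium

Calcium activity extraction from scanless light-field microscopy (LFM)
videos, for labs doing fast volumetric imaging of neuronal populations with
a microlens-array microscope — and for anyone who wants a fully synthetic,
ground-truthed testbed for LFM calcium pipelines.

A light-field microscope records an entire 3D volume in every camera frame:
a microlens array (MLA) at the native image plane turns each lenslet into
one lateral sample with many angular samples, so a single 2D frame `F`
encodes a volume `v` through a linear operator, `F = A v`. lfcalcium
implements the full computational chain around that model:

* **Forward model** — a per-depth lenslet filter bank `A` built from the
  optical configuration (pitch, magnification, MLA f-number, z-grid), with
  `forward_project()` / `back_project()` as an exactly adjoint pair, plus
  the closed-form optics calculators (native lateral resolution
  `pitch / M`, resolvable spots per lenslet, the ~1.5 dB SNR cost per speed
  doubling, axial span of the z-grid).
* **Reconstruction** — Richardson-Lucy deconvolution
  (`v <- v * A'(F / Av) / A'1`, 8 iterations, backprojection start) and a
  sparsity-promoting ISTA/FISTA solver for
  `min 0.5||Av - F||^2 + lambda ||v||_1, v >= 0`.
* **Activity map** — the pixel-wise `max(dF)/sigma(F)` light field (x1024,
  median shifted to 16, truncated to [9, 150]) that turns a video into one
  high-contrast image of the active somata.
* **Segmentation** — 3D Voronoi-Otsu labeling (blurred local-maxima seeds,
  Otsu foreground, nearest-seed assignment) with physical-unit centroids.
* **Trace extraction** — the footprint *matrix method*
  (`S = pinv(Y) F`, with `Y` the stacked light-field footprints of the
  ROIs) and the *ROI method* (per-frame reconstruction, ROI-mean).
* **Quality metrics** — the z-scored 10-sample-smoothed SNR in dB, the 6 dB
  inclusion floor, greedy cross-method trace matching (< 20 um, r > 0.5),
  neighbor crosstalk tables (<= 50 um), block-average downsampling.
* **Dynamics** — AR(1) nonnegative spike deconvolution (OASIS-style
  pool-adjacent-violators), putative-spike detection, agglomerative
  clustering of deconvolved traces (~6 per cluster), and within/between
  cluster distance tests.
* **Synthetic data** — a generator that places spiking somata in the
  volume, renders noisy 8-bit LF videos through the forward model
  (depth-dependent scattering blur, haze, Poisson + read noise, dark level
  9) and keeps every piece of ground truth for scoring.

See `vignettes/lfcalcium-methods.Rmd` for the models, parameter choices and
limitations, and `inst/cli/lfcalcium.R` for a command-line front end
(`simulate`, `activity-map`, `reconstruct`, `segment`, `extract`, `qc`,
`run`).

## Worked example

```r
library(lfcalcium)

cfg  <- demo_lfm_config()          # 24x24 lenslets, 5 px/lenslet, 13 z-planes
bank <- build_psf_bank(cfg)
res  <- run_pipeline(config = cfg, bank = bank, seed = 1)  # simulates a video

res$labels
#> <label_volume> 23 ROIs over 48 x 48 x 13 voxels
res$traces
#> <trace_set> 23 traces x 500 frames at 100 Hz (matrix, raw)
round(range(attr(res$traces, "snr_db")), 1)
#> [1] 10.7 12.5
head(roi_centroids_um(res$labels), 3)
#>          y_um     x_um      z_um
#> [1,] 24.97000  7.27000 -12.92800
#> [2,] 55.56973 16.30102 -11.72789
#> [3,] 25.81395 44.56395 -12.13953
```

The pipeline renders a 5-s, 100-Hz video of 25 spiking somata, computes the
activity map, reconstructs it (8-iteration RL), segments the somata,
demixes their traces with the footprint pseudoinverse, and keeps the traces
with SNR above 6 dB. Against the simulation's ground truth this run detects
the population with F1 ~ 0.92 at a one-lenslet (5 um) match radius and
recovers calcium traces with median correlation ~ 0.99.

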