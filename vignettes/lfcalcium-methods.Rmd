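---
title: "Models and methods behind lfcalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lfcalcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lfcalcium implements the computational chain of scanless light-field
microscopy (LFM) calcium imaging: from a raw video of rectified light fields
to demixed per-neuron calcium traces, inferred spike times and spatial
ensemble statistics. This vignette explains the models, the tunable
parameters and the design decisions, in the order the pipeline runs them.

## The linear forward model

An LFM places a microlens array (MLA) at the native image plane of a
widefield microscope; the camera, conjugated to the MLA back focal plane,
records a *light field* `F`: each lenslet's sub-image samples one lateral
location across many propagation angles. The map from a 3D fluorescence
distribution `v` to the sensor is linear, `F = A v`, and lfcalcium
represents `A` as a per-depth filter bank.

The default `"geometric"` bank ray-traces the acceptance cone of a lenslet:
the object-side half-angle is `tan(alpha) = M / (2 f#)` with `M` the
objective magnification and `f#` the MLA f-number. Each within-lenslet pixel
is one angular sample `a` inside that cone, and a point source at lateral
position `u` and defocus `z` sends the ray with angle `a` to lenslet
coordinate `u + z a` — the epipolar-line geometry of a light field. Energy is
split bilinearly between neighboring lenslets, blurred with a small
anti-alias Gaussian (sigma 0.5 px), and normalized so every depth kernel has
unit sum. Consequences that the test suite checks directly:

* at `z = 0` the whole footprint falls inside the source's lenslet;
* the footprint of a source translated by one lenslet pitch translates by
  exactly `pixels_per_lenslet` pixels (periodicity);
* the lenslet-space centroid of energy at a fixed angular pixel moves
  linearly in `z` (disparity);
* `forward_project()` and `back_project()` are exact adjoints, because both
  are applications of one sparse matrix and its transpose.

`"fresnel"` mode additionally convolves each kernel with a Gaussian
approximation of the diffraction-limited MLA-aperture spot
(`sigma = 0.45 lambda f# / pixel`); it is not a full scalar-diffraction
propagator. No mode attempts to reproduce a real instrument's calibrated
PSF — the bank exists to give every downstream stage an exactly linear,
energy-conserving operator whose properties are provable at test time.

The closed-form calculators hold for any configuration: the native lateral
resolution is the lenslet pitch referred to object space (`125 um / 25x =
5 um` for the reference instrument); the number of resolvable spots behind a
lenslet is the pitch divided by the larger of the diffraction spot and the
camera pixel (`floor(125 / 6.5) = 19`); shot-noise-limited imaging loses
`10 log10(sqrt(2)) ~ 1.5 dB` of SNR per speed doubling; and the 53-plane,
2-um-step reconstruction grid spans 104 um axially.

## Volume reconstruction

Two model-based solvers invert `F = A v`:

* **Richardson-Lucy** (`richardson_lucy()`): the multiplicative update
  `v <- v * A'(F / A v) / A' 1`, initialized with the backprojection `A' F`,
  8 iterations by default. Iterates are nonnegative by construction; the
  ratio is guarded by `eps = 1e-12`. With unit-sum kernels the weighted flux
  `sum((A'1) v)` equals the light-field flux after the first iteration, so
  interior phantoms conserve total intensity to well under 1%.
* **ISTA / FISTA** (`ista_reconstruct()`): proximal gradient descent on
  `0.5 ||A v - F||^2 + lambda ||v||_1` with `v >= 0`. The step defaults to
  `1/L` with `L` the largest eigenvalue of `A'A` estimated by power
  iteration (with a 5% safety margin, so the plain ISTA objective is
  provably monotone; two consecutive increases raise a step-size error).
  This is the classical form of the sparsity-promoting optimization that
  physics-based unrolled networks implement layer by layer; compact somata
  make calcium activity volumes naturally sparse, and on matched phantoms
  the sparse solution leaves measurably less background energy than
  8-iteration RL.

`lambda` is specified in absolute units; the pipeline scales it as a
fraction (`lambda_rel`, default 0.02) of `max(A'F)`, the largest value that
does not zero the solution.

## Activity map

`compute_activity_map()` collapses a video into one high-contrast light
field, pixel by pixel: smooth the time series with a size-3 uniform filter
(reflecting boundaries), take the range of the smoothed trace (`max(dF)`
over a minimum baseline; a percentile baseline is available), divide by the
standard deviation of the *unfiltered* series, multiply by 1024, shift so
the image median lands at gray level 16, and truncate to `[9, 150]` — 9
being the camera dark value on an 8-bit scale. Active somata saturate at
150 while the background median stays at 16. Because the scaling factor is
large, background pixels spread widely around the median; the map is a
detection image, not a photometric one. Pixels with zero temporal variance
are set to the dark value.

## Segmentation

`voronoi_otsu_label()` follows the Voronoi-Otsu scheme: local maxima of the
`sigma_spot`-blurred volume seed the labels (plateaus collapse to one seed,
lowest linear index, so results are deterministic), Otsu's threshold (256
bins) on the `sigma_outline`-blurred volume defines the foreground, and
every foreground voxel joins its nearest seed. Sigmas are in voxel units
and accept per-axis values; the pipeline scales the axial sigma by the
voxel aspect ratio so the blur is isotropic in micrometers (the reference
description uses sigma_spot 3, sigma_outline 1 on a nearly isotropic grid).
Two refinements sharpen the unweighted centroids that downstream matching
uses: ROIs smaller than `min_voxels` are dropped (pipeline default 8), and
with `peak_frac > 0` (pipeline default 0.3) each Voronoi cell is trimmed to
the voxels reaching that fraction of its peak intensity, which removes the
reconstruction halo that otherwise drags centroids axially. Each label is
finally reduced to the connected component containing its brightest voxel.

## Trace extraction

Two extraction methods mirror the two reconstruction-based workflows:

* **Matrix method** (`build_footprint_matrix()` + `extract_matrix_traces()`):
  each ROI is painted into an 8-bit-style volume (ROI voxels at 150),
  projected to its light-field *footprint*, and the vectorized footprints
  form the columns of `Y`. The calcium time series are `S = pinv(Y) F` —
  per-frame least squares, with the pseudoinverse computed by SVD under a
  relative singular-value cutoff of `1e-10` (rank deficiency produces a
  warning and minimum-norm traces). The video's dark level is subtracted
  before demixing. With a noiseless mixture and full-rank footprints the
  recovery is exact to floating point.
* **ROI method** (`reconstruct_video()` + `extract_roi_traces()`): every
  frame is reconstructed (RL or sparse) and each trace is the mean intensity
  of the ROI's voxels per frame.

`normalize_ds_over_s()` maps traces to `S(t)/mean(S) - 1`, the scale- and
offset-free form used for cross-method display.

## Quality metrics

`snr_db()` implements the trace SNR definition used throughout: z-score the
trace, smooth with a size-10 uniform filter, let `N` be the SD of the
(smoothed minus unfiltered) residual and `S` the range of the smoothed
trace, and report `10 log10(S/N)`. The factor is 10 (not 20) by definition
of this statistic, and the z-scoring makes it invariant to affine
transforms. `filter_by_snr()` keeps traces strictly above 6 dB, the floor
that excludes noise-dominated false positives. `match_traces()` pairs two
trace sets greedily by increasing centroid distance under a 20-um gate and
keeps pairs with Pearson r > 0.5; `neighbor_crosstalk()` tabulates all
pairs within 50 um with their raw-trace correlation and mean pair depth;
`downsample_average()` takes non-overlapping block means, which boosts
white-noise SNR by the square root of the factor at the price of temporal
resolution.

## Spike inference and ensembles

`oasis_ar1()` solves the AR(1) nonnegative deconvolution
`min 0.5 ||c - y||^2 + lambda sum(s)`, `s(t) = c(t) - gamma c(t-1) >= 0`,
with the online pool-adjacent-violators scheme; the fitted calcium obeys the
AR(1) recursion identically, and the test suite cross-checks the solution
against an independent nonnegative-lasso oracle. A natural `gamma` for an
indicator with decay constant `tau` at frame rate `f` is `exp(-1/(f tau))`;
the pipeline uses `tau = 0.15 s`. `detect_putative_spikes()` takes local
maxima of the inferred activity above a fraction of its peak and, because a
finite indicator rise spreads one spike's activity over the rising-phase
frames, reports each detection at the onset of its monotone ascent — the
first frame the event touches. `cluster_traces()` groups deconvolved traces
by average-linkage hierarchical clustering on the correlation distance
`1 - r`, cutting the tree at about six traces per cluster
(`k = round(n/6)`), and `intra_inter_distance_test()` compares within- versus
between-cluster centroid distances with two-sided Mann-Whitney U and t
tests — spatially intermingled ensembles yield indistinguishable
distributions.

## The synthetic study

The generator exists so every stage is testable against ground truth
without any external data. Its defaults define one fixed set of study
conditions:

* geometry: the `demo_lfm_config()` desk-scale instrument — 24 x 24
  lenslets, 5 px/lenslet, supersampling 2, 13 planes at 4 um (a
  120 x 120 x 48 um volume at 2.5 um lateral voxels). These sizes keep a
  full pipeline run near ten seconds on one CPU while preserving the
  native-plane-centered, lenslet-periodic geometry of the full-scale
  instrument;
* population: 25 somata of radius 6 um, at least 26 um apart, which matches
  the active-cell density of the recordings the pipeline targets (tens of
  active cells in a few hundred micrometers of cortex);
* dynamics: homogeneous Poisson spiking at 10 Hz for 5 s at 100 Hz frames;
  difference-of-exponentials calcium kinetics with rise 5 ms and decay
  150 ms. The rise sits at the fast end of published jGCaMP8f estimates and
  puts the time-to-peak near 17 ms (2-3 samples of rising phase at 100 Hz),
  which is what makes +-10 ms spike timing a meaningful target at this
  frame rate;
* optics and camera: depth-dependent Gaussian scattering blur (1 um at the
  shallowest plane growing by 0.04 um per um of depth), 10% uniform haze,
  Poisson shot noise, Gaussian read noise (sd 1 count), dark level 9,
  rounding to 8 bits. The soma brightness default (12 counts per unit
  fluorescence) was chosen so that extracted traces land near 12 dB median
  SNR — the regime the SNR metric and the 6 dB floor were designed for.

Rendering exploits linearity: each neuron's static scattered footprint is
projected once and scaled by its fluorescence per frame, which is exactly
equivalent to painting and projecting full volumes frame by frame.

What the generator does *not* emulate: neuropil and dendrites, indicator
nonlinearity and saturation, amplitude variability across spikes, motion,
aberrations, or realistic speckle-like scattering. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as the
theory predicts under a faithful linear image-formation model — not that
they meet any particular performance number on real tissue.

The worst-case crosstalk scenario (`simulate_adjacent_pair()`) places two
independently firing somata overlapping laterally and separated axially by
one reconstruction z-step, i.e. at the axial sampling limit where their
footprints are most collinear — the desk-scale analog of two cells touching
axially under an instrument whose axial resolution they undercut. Per-frame
sparse reconstruction separates such pairs better than 8-iteration RL: the
ROI-mean traces of the pair are less correlated under the sparse solver in
the large majority of random repeats, reproducing at desk scale the
qualitative ordering observed with unrolled-network reconstructions on real
recordings.

## Numerical choices and edge cases

* Zero padding at the sensor border: sources within one defocus-disk radius
  of the edge lose energy; energy-conservation statements hold for interior
  sources only.
* RL guards the Poisson ratio with `eps = 1e-12`; voxels invisible to the
  sensor (zero operator column) stay zero.
* The power-iteration Lipschitz estimate is inflated by 5% before the step
  size is formed.
* Otsu ties resolve to the first histogram maximum; plateau maxima collapse
  to the lowest linear index; both make segmentation deterministic.
* All randomness flows from one integer master seed through fixed
  sub-stream derivation, so every simulation, pipeline run and manifest is
  bit-reproducible.
* Trace-to-truth spike comparisons align a continuous spike time `t` to the
  first frame it can affect (`floor(t f) + 2` in 1-based indexing, for
  frames stamped at `(k-1)/f`).

## Known limitations

The geometric PSF is an idealization: no wave optics, no depth-dependent
aberrations, and angular sampling limited to `pixels_per_lenslet^2` rays.
The per-frame sparse solver is a classical ISTA, not a trained network; it
shares the objective the learned reconstruction unrolls but none of its
learned priors, so it under-performs such methods on real, scattering
tissue. Segmentation assumes blob-like somata and will not follow
dendrites. The pseudoinverse demixing has no nonnegativity or background
term; heavily overlapping footprints produce noisier traces rather than
failing loudly (watch `condition_estimate`). HDF5 interchange is not
provided; multi-page TIFF, CSV, JSON and YAML cover all inputs and outputs.
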