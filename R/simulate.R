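#' Simulate Poisson spike trains
#'
#' Homogeneous Poisson spiking for a population of neurons. Deterministic
#' given `seed`.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param rate_hz Mean firing rate (Hz, >= 0).
#' @param duration_s Recording duration (s).
#' @param seed Integer seed.
#' @return List of length `n_neurons`; each element a sorted numeric vector of
#'   spike times in `[0, duration_s]`.
#' @export
simulate_spikes <- function(n_neurons, rate_hz, duration_s, seed = 1L) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0", call. = FALSE)
  if (n_neurons < 1) stop("`n_neurons` must be >= 1", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_neurons), function(i) {
    n <- stats::rpois(1L, rate_hz * duration_s)
    sort(stats::runif(n, 0, duration_s))
  })
}

# Double-exponential calcium impulse response, peak-normalized to 1.
calcium_kernel <- function(t, rise_tau_s, decay_tau_s) {
  k <- ifelse(t >= 0, exp(-t / decay_tau_s) - exp(-t / rise_tau_s), 0)
  t_peak <- log(decay_tau_s / rise_tau_s) * rise_tau_s * decay_tau_s /
    (decay_tau_s - rise_tau_s)
  k / (exp(-t_peak / decay_tau_s) - exp(-t_peak / rise_tau_s))
}

#' Convert spike times to a sampled calcium fluorescence trace
#'
#' Convolves a spike train with a difference-of-exponentials indicator
#' response (peak amplitude `amplitude` per spike), evaluated in continuous
#' time at the frame sampling instants. The defaults emulate a fast GECI
#' (jGCaMP8f-like): rise constant 5 ms and decay 150 ms put the time to peak
#' near 17 ms, so the rising phase of a transient spans 2-3 samples at the
#' 100 Hz frame rate.
#'
#' @param spikes Numeric vector of spike times (s), or a list of such vectors.
#' @param rise_tau_s,decay_tau_s Rise and decay time constants (s),
#'   `0 < rise < decay`.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param duration_s Trace duration (s); frames at `(0:(T-1))/frame_rate_hz`.
#' @param amplitude Fluorescence increment per spike (a.u.).
#' @return Numeric vector of length `floor(duration_s * frame_rate_hz)` (or a
#'   matrix, neurons x frames, for list input).
#' @export
spikes_to_calcium <- function(spikes, rise_tau_s = 0.005, decay_tau_s = 0.15,
                              frame_rate_hz = 100, duration_s = 5,
                              amplitude = 1) {
  if (rise_tau_s <= 0 || decay_tau_s <= 0 || rise_tau_s >= decay_tau_s)
    stop("need 0 < rise_tau_s < decay_tau_s", call. = FALSE)
  n_t <- as.integer(floor(duration_s * frame_rate_hz))
  tt <- (seq_len(n_t) - 1L) / frame_rate_hz
  one <- function(sp) {
    tr <- numeric(n_t)
    for (ts in sp) {
      tr <- tr + amplitude * calcium_kernel(tt - ts, rise_tau_s, decay_tau_s)
    }
    tr
  }
  if (is.list(spikes)) {
    do.call(rbind, lapply(spikes, one))
  } else {
    one(spikes)
  }
}

# Rejection-sample soma centers with a minimum pairwise distance inside the
# configuration volume, leaving a margin on every face.
place_somata <- function(n, config, min_dist_um = 20, margin_um = 8,
                         seed = 1L, max_tries = 20000L) {
  set.seed(seed)
  lat_y <- config$n_lenslets_y * lenslet_pitch_object_um(config)
  lat_x <- config$n_lenslets_x * lenslet_pitch_object_um(config)
  zr <- range(z_depths_um(config))
  zm <- min(margin_um, (zr[2] - zr[1]) / 2 * 0.49)
  centers <- matrix(NA_real_, n, 3L,
                    dimnames = list(NULL, c("y_um", "x_um", "z_um")))
  placed <- 0L
  for (i in seq_len(max_tries)) {
    p <- c(stats::runif(1, margin_um, lat_y - margin_um),
           stats::runif(1, margin_um, lat_x - margin_um),
           stats::runif(1, zr[1] + zm, zr[2] - zm))
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                               2, p)^2))) >= min_dist_um) {
      placed <- placed + 1L
      centers[placed, ] <- p
      if (placed == n) return(centers)
    }
  }
  stop("could not place ", n, " somata with min distance ", min_dist_um,
       " um; reduce density", call. = FALSE)
}

# Paint one soma (soft-edged sphere) onto the configuration voxel grid.
paint_soma <- function(center_um, radius_um, config, edge_um = NULL) {
  vd <- volume_dim(config)
  vl <- lateral_voxel_um(config)
  if (is.null(edge_um)) edge_um <- vl
  yy <- (seq_len(vd[1]) - 0.5) * vl
  xx <- (seq_len(vd[2]) - 0.5) * vl
  zz <- z_depths_um(config)
  dy2 <- (yy - center_um[1])^2
  dx2 <- (xx - center_um[2])^2
  dz2 <- (zz - center_um[3])^2
  d <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
  stats::pnorm((radius_um - d) / edge_um)
}

# Depth-dependent lateral scattering blur: sigma grows linearly with depth
# below the top (shallowest) reconstruction plane.
scatter_blur_volume <- function(vol, config, surface_sigma_um = 1,
                                growth_per_um = 0.04) {
  vl <- lateral_voxel_um(config)
  zz <- z_depths_um(config)
  depth <- zz - min(zz)
  out <- vol
  for (k in seq_along(zz)) {
    sg <- (surface_sigma_um + growth_per_um * depth[k]) / vl
    if (sg > 0) out[, , k] <- gauss_blur_2d(vol[, , k], sg)
  }
  out
}

#' Simulate a ground-truth population of spiking somata
#'
#' Places somata in the reconstruction volume, draws Poisson spike trains and
#' converts them to calcium fluorescence traces. The result, together with
#' [render_lf_video()], emulates a light-field recording of spontaneously
#' active neurons corrupted by depth-dependent scattering and camera noise,
#' and carries everything needed to score detection and trace recovery
#' downstream.
#'
#' @param config An [lfm_config()].
#' @param n_neurons Number of somata.
#' @param rate_hz Poisson firing rate per neuron (Hz).
#' @param duration_s Recording length (s).
#' @param soma_radius_um Soma radius (um).
#' @param min_dist_um Minimum pairwise center distance (um).
#' @param rise_tau_s,decay_tau_s Indicator kinetics (s).
#' @param amplitude Fluorescence increment per spike, relative units.
#' @param f0 Resting fluorescence relative to a unit-amplitude transient.
#' @param brightness Photon flux scale: expected sensor counts contributed by
#'   one soma voxel at unit fluorescence.
#' @param noise List: `photon_scale` (photons per camera count; larger means
#'   less shot noise), `read_noise_sd` (counts), `dark_level` (counts).
#' @param scatter List: `surface_sigma_um`, `growth_per_um`,
#'   `background_fraction`.
#' @param seed Master seed (placement and spiking).
#' @return A `lf_ground_truth` object.
#' @export
simulate_ground_truth <- function(config = demo_lfm_config(),
                                  n_neurons = 25L, rate_hz = 10,
                                  duration_s = 5, soma_radius_um = 6,
                                  min_dist_um = 26,
                                  rise_tau_s = 0.005, decay_tau_s = 0.15,
                                  amplitude = 1, f0 = 0.3, brightness = 12,
                                  noise = list(photon_scale = 1,
                                               read_noise_sd = 1,
                                               dark_level = 9),
                                  scatter = list(surface_sigma_um = 1,
                                                 growth_per_um = 0.04,
                                                 background_fraction = 0.1),
                                  seed = 1L) {
  centers <- place_somata(n_neurons, config, min_dist_um = min_dist_um,
                          seed = derive_seed(seed, 1L))
  spikes <- simulate_spikes(n_neurons, rate_hz, duration_s,
                            seed = derive_seed(seed, 2L))
  calcium <- spikes_to_calcium(spikes, rise_tau_s, decay_tau_s,
                               config$frame_rate_hz, duration_s, amplitude)
  structure(list(config = config, centers = centers,
                 soma_radius_um = soma_radius_um, spikes = spikes,
                 calcium = calcium, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, amplitude = amplitude, f0 = f0,
                 brightness = brightness, noise = noise, scatter = scatter,
                 duration_s = duration_s, seed = seed),
            class = "lf_ground_truth")
}

#' @export
print.lf_ground_truth <- function(x, ...) {
  cat(sprintf("<lf_ground_truth> %d somata, %g s at %g Hz, %d spikes total\n",
              nrow(x$centers), x$duration_s, x$config$frame_rate_hz,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Per-neuron ground-truth light-field footprints
#'
#' Paints each soma, applies the depth-dependent scattering blur, and pushes
#' it through the forward model, giving the static sensor footprint whose
#' amplitude is modulated by the neuron's fluorescence during rendering.
#'
#' @param gt A [simulate_ground_truth()] object.
#' @param bank A [build_psf_bank()] for the same configuration.
#' @return `n_pixels x n_neurons` matrix of vectorized footprints.
#' @export
ground_truth_footprints <- function(gt, bank) {
  cfg <- gt$config
  A <- forward_operator(bank)
  n <- nrow(gt$centers)
  V <- matrix(0, prod(volume_dim(cfg)), n)
  for (i in seq_len(n)) {
    vol <- paint_soma(gt$centers[i, ], gt$soma_radius_um, cfg)
    vol <- scatter_blur_volume(vol, cfg, gt$scatter$surface_sigma_um,
                               gt$scatter$growth_per_um)
    V[, i] <- as.vector(vol)
  }
  as.matrix(A %*% V)
}

#' Ground-truth ROI label volume
#'
#' Paints every simulated soma as a hard sphere on the reconstruction grid
#' and labels it with the neuron index (overlap voxels go to the nearer
#' soma). These oracle ROIs let trace extraction be scored independently of
#' the segmentation stage.
#'
#' @param gt A [simulate_ground_truth()] object.
#' @param level Soma profile level defining the sphere boundary (default 0.5,
#'   i.e. the nominal radius).
#' @return A [label_volume()].
#' @export
ground_truth_labels <- function(gt, level = 0.5) {
  cfg <- gt$config
  lab <- array(0L, volume_dim(cfg))
  best <- array(0, volume_dim(cfg))
  for (i in seq_len(nrow(gt$centers))) {
    p <- paint_soma(gt$centers[i, ], gt$soma_radius_um, cfg)
    sel <- p > level & p > best
    lab[sel] <- i
    best[sel] <- p[sel]
  }
  label_volume(lab, config = cfg)
}

#' Render a noisy light-field video from ground truth
#'
#' Forms, per frame, the linear combination of each neuron's static scattered
#' footprint weighted by its fluorescence `brightness * (f0 + calcium(t))`,
#' adds a uniform background haze, then applies Poisson shot noise (at
#' `photon_scale` photons per count), Gaussian read noise and the camera dark
#' level, and optionally quantizes to the requested bit depth. Because the
#' scattering blur and the forward projection are both linear and the soma
#' profiles static, this per-footprint rendering is exactly equivalent to
#' painting and projecting full volumes frame by frame.
#'
#' @param gt A [simulate_ground_truth()] object.
#' @param bank A [build_psf_bank()] for `gt$config`.
#' @param seed Integer seed for the noise stream.
#' @param noiseless If `TRUE`, skip all noise and quantization and return the
#'   expected counts plus dark level.
#' @param bit_depth 8 (default), 16, or `"float"` (no quantization).
#' @return An [lf_video()]; frames are `H x W x T` counts.
#' @export
render_lf_video <- function(gt, bank, seed = 1L, noiseless = FALSE,
                            bit_depth = 8) {
  cfg <- gt$config
  if (!identical(volume_dim(cfg), volume_dim(bank$config)))
    stop("ground truth and PSF bank configurations disagree", call. = FALSE)
  fps <- ground_truth_footprints(gt, bank)        # n_px x n
  amps <- gt$brightness * (gt$f0 + gt$calcium)    # n x T
  lam <- fps %*% amps                             # n_px x T expected counts
  haze <- gt$scatter$background_fraction * mean(fps %*% rep(gt$brightness * gt$f0,
                                                            nrow(gt$centers)))
  lam <- lam + haze
  dark <- gt$noise$dark_level
  if (noiseless) {
    frames <- lam + dark
  } else {
    set.seed(derive_seed(seed, 99L))
    P <- gt$noise$photon_scale
    counts <- matrix(stats::rpois(length(lam), as.vector(lam) * P) / P,
                     nrow(lam), ncol(lam))
    counts <- counts + stats::rnorm(length(counts), 0, gt$noise$read_noise_sd)
    frames <- counts + dark
    if (!identical(bit_depth, "float")) {
      top <- 2^as.integer(bit_depth) - 1
      frames <- round(pmin(pmax(frames, 0), top))
    }
  }
  sd2 <- sensor_dim(cfg)
  lf_video(array(frames, c(sd2[1], sd2[2], ncol(lam))),
           frame_rate_hz = cfg$frame_rate_hz, bit_depth = bit_depth,
           dark_level = dark)
}

#' Worst-case adjacent-pair crosstalk scenario
#'
#' Ground truth for the optical-crosstalk benchmark: two somata overlapping
#' laterally and separated axially by one reconstruction z-step -- at the
#' axial sampling limit of the instrument, where their light-field footprints
#' are nearly collinear and per-frame reconstruction mixes their signals the
#' most. The two neurons fire independent Poisson spike trains, so any excess
#' correlation between their extracted traces measures optical crosstalk, not
#' shared activity.
#'
#' @param config An [lfm_config()]; the pair is centered laterally.
#' @param rate_hz Firing rate of each neuron (Hz).
#' @param duration_s Recording length (s).
#' @param dz_um Axial center separation (um); defaults to one z-step.
#' @param lateral_offset_um Half lateral offset of each soma from the center
#'   line (um).
#' @param zmid_um Mean pair depth relative to the focal plane (um).
#' @param seed Master seed.
#' @param ... Passed to [simulate_ground_truth()] (noise, scatter, kinetics).
#' @return An `lf_ground_truth` with exactly two neurons.
#' @export
simulate_adjacent_pair <- function(config = demo_lfm_config(n_lenslets = 10L,
                                                            n_z = 9L,
                                                            z_step_um = 5,
                                                            lateral_supersampling = 1L),
                                   rate_hz = 8, duration_s = 2,
                                   dz_um = config$z_step_um,
                                   lateral_offset_um = 1.5, zmid_um = 0,
                                   seed = 1L, ...) {
  gt <- simulate_ground_truth(config, n_neurons = 2L, rate_hz = rate_hz,
                              duration_s = duration_s, seed = seed, ...)
  cy <- config$n_lenslets_y * lenslet_pitch_object_um(config) / 2
  cx <- config$n_lenslets_x * lenslet_pitch_object_um(config) / 2
  gt$centers <- rbind(c(cy, cx - lateral_offset_um, zmid_um - dz_um / 2),
                      c(cy, cx + lateral_offset_um, zmid_um + dz_um / 2))
  rownames(gt$centers) <- NULL
  gt
}
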