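#' LFM optical and sampling configuration
#'
#' Bundles the geometry of a light-field microscope (LFM) with the sampling of
#' the reconstruction grid. Lengths are in micrometers. The sensor is assumed
#' rectified: each lenslet spans exactly `pixels_per_lenslet` pixels per axis,
#' and the reconstruction volume has `n_lenslets * lateral_supersampling`
#' voxels per lateral axis and `n_z` planes spaced `z_step_um` apart, centered
#' on the native focal plane.
#'
#' The defaults describe the reference instrument this package models: a
#' 125-um-pitch f/10 microlens array behind a 25x objective, 6.5-um camera
#' pixels, 19 rectified pixels per lenslet, and a 53-plane, 2-um-step
#' reconstruction grid spanning 104 um axially.
#'
#' @param lenslet_pitch_um Microlens pitch at the native image plane (um).
#' @param magnification Objective magnification (dimensionless, > 0).
#' @param camera_pixel_um Physical camera pixel size (um).
#' @param pixels_per_lenslet Rectified pixels per lenslet per axis (odd, >= 3).
#' @param emission_wavelength_um Mean emission wavelength (um).
#' @param mla_f_number Microlens f-number (dimensionless).
#' @param n_lenslets_y,n_lenslets_x Lenslet counts per axis.
#' @param z_step_um Axial plane spacing of the reconstruction grid (um).
#' @param n_z Number of reconstruction planes (odd; the central plane is the
#'   native focal plane).
#' @param lateral_supersampling Voxels per lenslet per lateral axis in the
#'   reconstruction grid (integer >= 1).
#' @param frame_rate_hz Acquisition frame rate (Hz).
#' @return An object of class `lfm_config`.
#' @examples
#' cfg <- lfm_config()
#' native_lateral_resolution(cfg)
#' @export
lfm_config <- function(lenslet_pitch_um = 125,
                       magnification = 25,
                       camera_pixel_um = 6.5,
                       pixels_per_lenslet = 19L,
                       emission_wavelength_um = 0.53,
                       mla_f_number = 10,
                       n_lenslets_y = 107L,
                       n_lenslets_x = 107L,
                       z_step_um = 2,
                       n_z = 53L,
                       lateral_supersampling = 2L,
                       frame_rate_hz = 100) {
  cfg <- list(
    lenslet_pitch_um = lenslet_pitch_um,
    magnification = magnification,
    camera_pixel_um = camera_pixel_um,
    pixels_per_lenslet = as.integer(pixels_per_lenslet),
    emission_wavelength_um = emission_wavelength_um,
    mla_f_number = mla_f_number,
    n_lenslets_y = as.integer(n_lenslets_y),
    n_lenslets_x = as.integer(n_lenslets_x),
    z_step_um = z_step_um,
    n_z = as.integer(n_z),
    lateral_supersampling = as.integer(lateral_supersampling),
    frame_rate_hz = frame_rate_hz
  )
  class(cfg) <- "lfm_config"
  validate_lfm_config(cfg)
  cfg
}

validate_lfm_config <- function(cfg) {
  lens <- c("lenslet_pitch_um", "camera_pixel_um", "emission_wavelength_um",
            "z_step_um")
  for (f in lens) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("invalid LFM config: `", f, "` must be a positive length", call. = FALSE)
  }
  if (!is.numeric(cfg$magnification) || cfg$magnification <= 0)
    stop("invalid LFM config: `magnification` must be > 0", call. = FALSE)
  if (cfg$mla_f_number <= 0)
    stop("invalid LFM config: `mla_f_number` must be > 0", call. = FALSE)
  if (cfg$pixels_per_lenslet < 3L || cfg$pixels_per_lenslet %% 2L == 0L)
    stop("invalid LFM config: `pixels_per_lenslet` must be odd and >= 3", call. = FALSE)
  if (cfg$n_z < 1L || cfg$n_z %% 2L == 0L)
    stop("invalid LFM config: `n_z` must be odd (central plane at focus)", call. = FALSE)
  if (cfg$n_lenslets_y < 1L || cfg$n_lenslets_x < 1L)
    stop("invalid LFM config: lenslet counts must be >= 1", call. = FALSE)
  if (cfg$lateral_supersampling < 1L)
    stop("invalid LFM config: `lateral_supersampling` must be >= 1", call. = FALSE)
  if (cfg$frame_rate_hz <= 0)
    stop("invalid LFM config: `frame_rate_hz` must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Desk-scale demonstration configuration
#'
#' A small configuration (24 x 24 lenslets, 5 pixels per lenslet, 13 planes at
#' 4 um) used by the bundled examples, tests and the synthetic study scenario.
#' It keeps the geometry of [lfm_config()] but at a scale where the forward
#' operator, reconstruction and full extraction pipeline run in seconds.
#'
#' @param n_lenslets Lenslets per axis.
#' @param n_z Number of z-planes (odd).
#' @param z_step_um Plane spacing (um).
#' @param lateral_supersampling Voxels per lenslet per lateral axis.
#' @param pixels_per_lenslet Rectified pixels per lenslet (odd).
#' @return An `lfm_config`.
#' @export
demo_lfm_config <- function(n_lenslets = 24L, n_z = 13L, z_step_um = 4,
                            lateral_supersampling = 2L,
                            pixels_per_lenslet = 5L) {
  lfm_config(n_lenslets_y = n_lenslets, n_lenslets_x = n_lenslets,
             pixels_per_lenslet = pixels_per_lenslet, n_z = n_z,
             z_step_um = z_step_um,
             lateral_supersampling = lateral_supersampling)
}

#' @export
print.lfm_config <- function(x, ...) {
  cat("<lfm_config>\n")
  cat(sprintf("  lenslets: %d x %d, %d px/lenslet (sensor %d x %d px)\n",
              x$n_lenslets_y, x$n_lenslets_x, x$pixels_per_lenslet,
              x$n_lenslets_y * x$pixels_per_lenslet,
              x$n_lenslets_x * x$pixels_per_lenslet))
  cat(sprintf("  pitch %.3g um / mag %.3g -> %.3g um per lenslet in object space\n",
              x$lenslet_pitch_um, x$magnification,
              lenslet_pitch_object_um(x)))
  cat(sprintf("  volume: %d x %d x %d voxels (%.3g um lateral, %.3g um axial step, %.3g um span)\n",
              x$n_lenslets_y * x$lateral_supersampling,
              x$n_lenslets_x * x$lateral_supersampling, x$n_z,
              lateral_voxel_um(x), x$z_step_um, axial_span_um(x)))
  cat(sprintf("  frame rate: %.3g Hz\n", x$frame_rate_hz))
  invisible(x)
}

# --- derived geometry -------------------------------------------------------

#' Derived geometry of an LFM configuration
#'
#' @param config An [lfm_config()].
#' @return `lenslet_pitch_object_um()`: lenslet pitch referred to object space
#'   (um); `lateral_voxel_um()`: lateral voxel size of the reconstruction grid
#'   (um); `axial_span_um()`: axial extent of the reconstruction grid (um);
#'   `z_depths_um()`: signed plane depths relative to the native focal plane
#'   (um); `sensor_dim()` / `volume_dim()`: integer dimensions.
#' @export
lenslet_pitch_object_um <- function(config) {
  config$lenslet_pitch_um / config$magnification
}

#' @rdname lenslet_pitch_object_um
#' @export
lateral_voxel_um <- function(config) {
  lenslet_pitch_object_um(config) / config$lateral_supersampling
}

#' @rdname lenslet_pitch_object_um
#' @export
axial_span_um <- function(config) {
  (config$n_z - 1L) * config$z_step_um
}

#' @rdname lenslet_pitch_object_um
#' @export
z_depths_um <- function(config) {
  (seq_len(config$n_z) - 1L - (config$n_z - 1L) / 2) * config$z_step_um
}

#' @rdname lenslet_pitch_object_um
#' @export
sensor_dim <- function(config) {
  c(config$n_lenslets_y, config$n_lenslets_x) * config$pixels_per_lenslet
}

#' @rdname lenslet_pitch_object_um
#' @export
volume_dim <- function(config) {
  c(config$n_lenslets_y * config$lateral_supersampling,
    config$n_lenslets_x * config$lateral_supersampling,
    config$n_z)
}

# --- closed-form optics calculators ----------------------------------------

#' Native lateral resolution of an LFM
#'
#' The native (pre-deconvolution) lateral resolution of a microlens-based LFM
#' is set by the lenslet sampling of the image plane: one lenslet pitch
#' referred back to object space, i.e. `lenslet_pitch / magnification`.
#'
#' @param config An [lfm_config()].
#' @return Resolution in micrometers.
#' @examples
#' native_lateral_resolution(lfm_config())  # 125/25 = 5 um
#' @export
native_lateral_resolution <- function(config) {
  validate_lfm_config(config)
  config$lenslet_pitch_um / config$magnification
}

#' Resolvable spots behind one lenslet
#'
#' The axial resolution of an LFM is governed by how many distinct
#' diffraction-limited spots fit behind each lenslet. The limiting sampler is
#' the larger of the diffraction spot and the camera pixel, so the count is
#' `floor(lenslet_pitch / max(spot_size, camera_pixel))`.
#'
#' @param config An [lfm_config()].
#' @param spot_size_um Diffraction-limited spot size at the camera plane (um).
#'   The 6.2-um default corresponds to a Sparrow-criterion spot at 530 nm
#'   behind an f/10 lenslet and is accepted as an input rather than recomputed.
#' @return Integer number of resolvable spots per lenslet.
#' @examples
#' resolvable_spots_per_lenslet(lfm_config())  # floor(125/6.5) = 19
#' @export
resolvable_spots_per_lenslet <- function(config, spot_size_um = 6.2) {
  validate_lfm_config(config)
  if (spot_size_um <= 0) stop("`spot_size_um` must be > 0", call. = FALSE)
  as.integer(floor(config$lenslet_pitch_um /
                     max(spot_size_um, config$camera_pixel_um)))
}

#' SNR penalty for faster acquisition
#'
#' Under shot-noise-limited imaging, SNR scales with the square root of the
#' exposure time, so speeding acquisition by `speed_factor` costs
#' `10*log10(sqrt(speed_factor))` decibels: about 1.5 dB per doubling.
#'
#' @param speed_factor Acquisition speed multiplier (>= 1); 2 means doubling
#'   the frame rate.
#' @return SNR loss in dB (positive).
#' @examples
#' snr_penalty_per_doubling()   # ~1.505 dB
#' snr_penalty_per_doubling(4)  # two doublings, ~3.01 dB
#' @export
snr_penalty_per_doubling <- function(speed_factor = 2) {
  if (speed_factor < 1) stop("`speed_factor` must be >= 1", call. = FALSE)
  10 * log10(sqrt(speed_factor))
}

# --- YAML (de)serialization -------------------------------------------------

#' Read or write an LFM configuration as YAML
#'
#' @param config An [lfm_config()].
#' @param path File path.
#' @return `read_lfm_config()` returns an `lfm_config`;
#'   `write_lfm_config()` returns `path` invisibly.
#' @export
write_lfm_config <- function(config, path) {
  validate_lfm_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_lfm_config
#' @export
read_lfm_config <- function(path) {
  do.call(lfm_config, yaml::read_yaml(path))
}

# Short hash of a configuration for provenance stamping of outputs.
config_hash <- function(config) {
  s <- paste(vapply(unclass(config), function(v) format(v, digits = 12),
                    character(1)), collapse = "|")
  raw <- utf8ToInt(s)
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
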