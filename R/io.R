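# Readers and writers for the interchange formats: multi-page TIFF for
# videos, light fields and label volumes; CSV for traces and QC tables; JSON
# for run manifests; YAML for configurations (see config.R).

#' Read and write light-field videos as multi-page TIFF
#'
#' Frames are stored as one TIFF page per time point at the requested bit
#' depth; integer counts round-trip losslessly. TIFF carries no frame-rate
#' tag, so `read_lf_video()` falls back to 100 Hz with a warning when no rate
#' is supplied.
#'
#' @param video An [lf_video()].
#' @param path TIFF file path.
#' @param frame_rate_hz Frame rate to attach on read; `NULL` means the 100 Hz
#'   default (with a warning).
#' @param dark_level Dark level to attach on read.
#' @param bit_depth 8 or 16 for writing.
#' @return `read_lf_video()`: an [lf_video()]; `write_lf_video()`: `path`,
#'   invisibly.
#' @export
write_lf_video <- function(video, path, bit_depth = video$bit_depth) {
  if (identical(bit_depth, "float")) bit_depth <- 16L
  bit_depth <- as.integer(bit_depth)
  top <- 2^bit_depth - 1
  fr <- video$frames
  pages <- lapply(seq_len(dim(fr)[3]),
                  function(t) pmin(pmax(fr[, , t], 0), top) / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "none")
  invisible(path)
}

#' @rdname write_lf_video
#' @export
read_lf_video <- function(path, frame_rate_hz = NULL, dark_level = 0) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("ragged TIFF stack: pages differ in size", call. = FALSE)
  fr <- array(0, c(d1[1], d1[2], length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]]
  if (is.null(frame_rate_hz)) {
    warning("no frame rate supplied; defaulting to 100 Hz")
    frame_rate_hz <- 100
  }
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  lf_video(fr, frame_rate_hz = frame_rate_hz, bit_depth = bits,
           dark_level = dark_level)
}

#' Write a light field or label volume as TIFF
#'
#' @param lf A [light_field()].
#' @param labels A [label_volume()] (written as 16-bit z-pages).
#' @param vol An [lfm_volume()] (float pages scaled to 16 bit).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_light_field <- function(lf, path) {
  bits <- if (identical(lf$bit_depth, 8) || identical(lf$bit_depth, 8L)) 8L else 16L
  top <- 2^bits - 1
  tiff::writeTIFF(pmin(pmax(lf$data, 0), top) / top, path,
                  bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' @rdname write_light_field
#' @export
read_light_field <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  light_field(m, bit_depth = attr(m, "bits.per.sample") %||% 16L)
}

#' @rdname write_light_field
#' @export
write_label_volume <- function(labels, path) {
  lab <- labels$labels
  pages <- lapply(seq_len(dim(lab)[3]), function(k) lab[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_light_field
#' @export
read_label_volume <- function(path, config = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  lab <- array(0L, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) lab[, , k] <- as.integer(pages[[k]])
  label_volume(lab, config = config)
}

#' @rdname write_light_field
#' @export
write_volume_tiff <- function(vol, path) {
  a <- as_volume_array(vol)
  mx <- max(a)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write traces to CSV (long format)
#'
#' One row per (roi, frame) with the trace value; includes the method tag and
#' centroid coordinates when available.
#'
#' @param ts A [trace_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(ts, path) {
  n <- nrow(ts$S); T <- ncol(ts$S)
  df <- data.frame(roi = rep(seq_len(n), each = T),
                   frame = rep(seq_len(T), times = n),
                   value = as.vector(t(ts$S)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Rectification calibration and resampling
#'
#' A raw light field is seldom aligned to an integer pixel grid: the measured
#' lenslet pitch is fractional (e.g. 125 um / 6.5 um = 19.23 px) and the MLA
#' may be slightly rotated. `rectify()` rotates and resamples (bilinear) the
#' raw frame so that each lenslet spans exactly `target_ppl` grid-aligned
#' pixels. Intensities are scaled by the pixel-area ratio so total intensity
#' is preserved (within interpolation error) over the common support.
#'
#' @param raw A [light_field()] or matrix.
#' @param lenslet_origin `(y, x)` pixel coordinates (1-based) of a reference
#'   lenslet center in the raw frame.
#' @param measured_pitch_px Lenslet pitch in raw pixels (> 1, may be
#'   fractional).
#' @param rotation_deg MLA rotation in degrees (|rotation| < 5).
#' @param target_ppl Integer pixels per lenslet in the output.
#' @param n_lenslets Output lenslet count per axis; `NULL` fits as many whole
#'   lenslets as the raw frame contains.
#' @return A [light_field()] of size `n_lenslets * target_ppl` per axis.
#' @export
rectify <- function(raw, lenslet_origin, measured_pitch_px, rotation_deg = 0,
                    target_ppl = NULL, n_lenslets = NULL) {
  m <- as_lf_matrix(raw)
  if (measured_pitch_px <= 1)
    stop("implausible calibration: `measured_pitch_px` must be > 1", call. = FALSE)
  if (abs(rotation_deg) >= 5)
    stop("implausible calibration: |rotation| must be < 5 degrees", call. = FALSE)
  if (is.null(target_ppl)) target_ppl <- round(measured_pitch_px)
  target_ppl <- as.integer(target_ppl)
  if (is.null(n_lenslets)) {
    n_lenslets <- floor(min(
      (nrow(m) - lenslet_origin[1]) / measured_pitch_px,
      (ncol(m) - lenslet_origin[2]) / measured_pitch_px) + 0.5) + 1L
    n_lenslets <- max(1L, n_lenslets)
  }
  out_n <- n_lenslets * target_ppl
  th <- rotation_deg * pi / 180
  # output pixel centers in lenslet coordinates, reference lenslet at (0, 0)
  u <- (seq_len(out_n) - 0.5) / target_ppl - 0.5
  gy <- matrix(u, out_n, out_n)
  gx <- matrix(u, out_n, out_n, byrow = TRUE)
  # map to raw pixel coordinates: scale by the measured pitch, rotate, shift
  ry <- lenslet_origin[1] + measured_pitch_px * (cos(th) * gy - sin(th) * gx)
  rx <- lenslet_origin[2] + measured_pitch_px * (sin(th) * gy + cos(th) * gx)
  out <- bilinear_sample(m, ry, rx) * (measured_pitch_px / target_ppl)^2
  light_field(matrix(out, out_n, out_n))
}

bilinear_sample <- function(m, ry, rx) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0;   fx <- rx - x0
  val <- 0
  for (q in 1:4) {
    yy <- y0 + (q == 2 | q == 4)
    xx <- x0 + (q == 3 | q == 4)
    wq <- switch(q, (1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
    inside <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[inside] <- m[cbind(yy[inside], xx[inside])]
    val <- val + wq * v
  }
  val
}
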