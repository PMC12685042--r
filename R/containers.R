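# Light containers shared across the pipeline. All are plain classed lists so
# that printing, subsetting and serialization stay transparent.

#' Light-field and volume containers
#'
#' A `light_field` is a single rectified 2D sensor frame; an `lf_video` is a
#' stack of frames (`H x W x T`); an `lfm_volume` is a reconstructed 3D
#' intensity grid on the configuration's voxel lattice, stored `(y, x, z)`.
#'
#' @param data Numeric matrix (light field) or 3D array (volume).
#' @param bit_depth 8, 16, or `"float"`.
#' @param dark_level Camera offset already contained in the counts.
#' @param config The [lfm_config()] the grid refers to.
#' @return The corresponding container object.
#' @export
light_field <- function(data, bit_depth = "float", dark_level = 0) {
  stopifnot(is.matrix(data))
  structure(list(data = data, bit_depth = bit_depth, dark_level = dark_level),
            class = "light_field")
}

#' @rdname light_field
#' @param frames `H x W x T` numeric array.
#' @param frame_rate_hz Acquisition rate in Hz.
#' @export
lf_video <- function(frames, frame_rate_hz = 100, bit_depth = "float",
                     dark_level = 0) {
  stopifnot(length(dim(frames)) == 3L)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 bit_depth = bit_depth, dark_level = dark_level),
            class = "lf_video")
}

#' @rdname light_field
#' @export
lfm_volume <- function(data, config) {
  stopifnot(length(dim(data)) == 3L)
  if (!all(dim(data) == volume_dim(config)))
    stop("volume dimensions do not match the configuration grid", call. = FALSE)
  if (min(data) < 0 && min(data) > -1e-9) data[data < 0] <- 0
  structure(list(data = data, config = config), class = "lfm_volume")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("<light_field> %d x %d px, bit depth %s, dark level %g\n",
              nrow(x$data), ncol(x$data), as.character(x$bit_depth),
              x$dark_level))
  invisible(x)
}

#' @export
print.lf_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<lf_video> %d frames of %d x %d px at %g Hz (bit depth %s, dark %g)\n",
              d[3], d[1], d[2], x$frame_rate_hz, as.character(x$bit_depth),
              x$dark_level))
  invisible(x)
}

#' @export
print.lfm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lfm_volume> %d x %d x %d voxels, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

# Coerce helpers used internally: accept either bare arrays or containers.
as_lf_matrix <- function(l) {
  if (inherits(l, "light_field")) l$data else as.matrix(l)
}

as_volume_array <- function(v) {
  if (inherits(v, "lfm_volume")) v$data else v
}

#' Vectorized frame matrix of a light-field video
#'
#' @param video An [lf_video()] or bare `H x W x T` array.
#' @return `n_pixels x n_frames` numeric matrix (frames as columns,
#'   column-major pixel order).
#' @export
video_matrix <- function(video) {
  fr <- if (inherits(video, "lf_video")) video$frames else video
  d <- dim(fr)
  matrix(fr, d[1] * d[2], d[3])
}
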