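#' Light-field footprint matrix
#'
#' For every ROI, builds an 8-bit-style volume that is zero everywhere except
#' the ROI voxels (set to `roi_value`, default 150), pushes it through the
#' forward model, and stacks the vectorized footprints as the columns of the
#' matrix `Y` used for pseudoinverse demixing.
#'
#' @param labels A [label_volume()] with at least one ROI.
#' @param bank A [build_psf_bank()] on the same grid.
#' @param roi_value Intensity written into ROI voxels before projection
#'   (default 150).
#' @return A `footprint_matrix`: list with `Y` (`n_pixels x n_rois`),
#'   `roi_ids`, `centroids_um` (if a config is available) and
#'   `condition_estimate` (ratio of extreme singular values).
#' @export
build_footprint_matrix <- function(labels, bank, roi_value = 150) {
  if (labels$n_rois < 1L)
    stop("label volume contains no ROIs", call. = FALSE)
  if (!all(dim(labels$labels) == volume_dim(bank$config)))
    stop("label volume grid does not match the PSF bank", call. = FALSE)
  A <- forward_operator(bank)
  n <- labels$n_rois
  idx <- which(labels$labels > 0L)
  M <- Matrix::sparseMatrix(i = idx, j = labels$labels[idx],
                            x = rep(roi_value, length(idx)),
                            dims = c(ncol(A), n))
  Y <- as.matrix(A %*% M)
  sv <- svd(Y, nu = 0, nv = 0)$d
  cent <- if (!is.null(labels$config)) roi_centroids_um(labels) else NULL
  structure(list(Y = Y, roi_ids = seq_len(n), centroids_um = cent,
                 condition_estimate = sv[1] / max(sv[length(sv)], .Machine$double.eps)),
            class = "footprint_matrix")
}

#' @export
print.footprint_matrix <- function(x, ...) {
  cat(sprintf("<footprint_matrix> %d pixels x %d ROIs, condition ~ %.3g\n",
              nrow(x$Y), ncol(x$Y), x$condition_estimate))
  invisible(x)
}

#' Extracted calcium trace set
#'
#' @param S `n_rois x n_frames` matrix of calcium time series.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param centroids_um Optional `n_rois x 3` matrix of centroids (um).
#' @param method_tag `"roi"`, `"matrix"`, `"rl"`, or free text.
#' @param normalization `"raw"` or `"ds_over_s"`.
#' @return A `trace_set`.
#' @export
trace_set <- function(S, frame_rate_hz, centroids_um = NULL,
                      method_tag = "raw", normalization = "raw") {
  S <- as.matrix(S)
  if (!is.null(centroids_um) && nrow(centroids_um) != nrow(S))
    stop("centroid count must equal trace count", call. = FALSE)
  structure(list(S = S, frame_rate_hz = frame_rate_hz,
                 centroids_um = centroids_um, method_tag = method_tag,
                 normalization = normalization),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d traces x %d frames at %g Hz (%s, %s)\n",
              nrow(x$S), ncol(x$S), x$frame_rate_hz, x$method_tag,
              x$normalization))
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD with a relative cutoff.
pseudoinverse <- function(Y, rel_tol = 1e-10) {
  sv <- svd(Y)
  keep <- sv$d > rel_tol * sv$d[1]
  if (!all(keep))
    warning("footprint matrix is numerically rank deficient (",
            sum(keep), "/", length(keep),
            " singular values kept); minimum-norm traces returned")
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Matrix-method trace extraction (footprint demixing)
#'
#' Computes the calcium time series as `S = pinv(Y) F`: a per-frame
#' least-squares fit of the light-field video onto the ROI footprints. With a
#' noiseless video that is an exact linear mixture of full-rank footprints,
#' the true time series are recovered to floating-point precision.
#'
#' @param fp A [build_footprint_matrix()] result.
#' @param video An [lf_video()] (or `n_pixels x T` matrix).
#' @param subtract_dark Subtract the video's dark level before demixing
#'   (default `TRUE`).
#' @param rel_tol Relative singular-value cutoff of the pseudoinverse.
#' @return A [trace_set()] with `method_tag = "matrix"`.
#' @export
extract_matrix_traces <- function(fp, video, subtract_dark = TRUE,
                                  rel_tol = 1e-10) {
  Fm <- if (inherits(video, "lf_video")) video_matrix(video) else as.matrix(video)
  if (nrow(Fm) != nrow(fp$Y))
    stop("video pixel count does not match the footprint matrix", call. = FALSE)
  if (nrow(Fm) < ncol(fp$Y))
    stop("need at least as many pixels as ROIs", call. = FALSE)
  if (subtract_dark && inherits(video, "lf_video"))
    Fm <- Fm - video$dark_level
  S <- pseudoinverse(fp$Y, rel_tol) %*% Fm
  fr <- if (inherits(video, "lf_video")) video$frame_rate_hz else NA_real_
  trace_set(S, frame_rate_hz = fr, centroids_um = fp$centroids_um,
            method_tag = "matrix")
}

#' ROI-mean trace extraction from a reconstructed volume series
#'
#' The trace of each ROI is the mean intensity of its voxels in every frame
#' of the reconstructed volume series.
#'
#' @param volume_series `n_voxels x n_frames` matrix (e.g. from
#'   [reconstruct_video()]) or a 4D `(y, x, z, t)` array.
#' @param labels A [label_volume()] on the same grid.
#' @param frame_rate_hz Sampling rate stored in the result.
#' @param method_tag Tag stored in the result (default `"roi"`).
#' @return A [trace_set()].
#' @export
extract_roi_traces <- function(volume_series, labels, frame_rate_hz = 100,
                               method_tag = "roi") {
  V <- if (length(dim(volume_series)) == 4L) {
    d <- dim(volume_series)
    matrix(volume_series, prod(d[1:3]), d[4])
  } else {
    as.matrix(volume_series)
  }
  if (nrow(V) != length(labels$labels))
    stop("volume series grid does not match the label volume", call. = FALSE)
  if (labels$n_rois < 1L) stop("label volume contains no ROIs", call. = FALSE)
  idx <- which(labels$labels > 0L)
  W <- Matrix::sparseMatrix(i = labels$labels[idx], j = idx,
                            x = 1 / labels$voxel_counts[labels$labels[idx]],
                            dims = c(labels$n_rois, nrow(V)))
  S <- as.matrix(W %*% V)
  cent <- if (!is.null(labels$config)) roi_centroids_um(labels) else NULL
  trace_set(S, frame_rate_hz = frame_rate_hz, centroids_um = cent,
            method_tag = method_tag)
}

#' Normalize traces to relative change about the temporal mean
#'
#' Maps each trace to `S(t) / mean(S) - 1`, the scale- and offset-comparable
#' form used to display traces extracted by different methods. The normalized
#' trace has zero temporal mean.
#'
#' @param ts A [trace_set()] with nonzero per-trace temporal means.
#' @return A [trace_set()] with `normalization = "ds_over_s"`.
#' @export
normalize_ds_over_s <- function(ts) {
  mu <- rowMeans(ts$S)
  if (any(mu == 0))
    stop("cannot normalize traces with zero temporal mean", call. = FALSE)
  out <- ts
  out$S <- ts$S / mu - 1
  out$normalization <- "ds_over_s"
  out
}
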