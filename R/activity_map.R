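#' Pixel-wise light-field activity map
#'
#' Collapses a light-field video into a single high-contrast light field in
#' which active neurons stand out. Per pixel: (1) smooth the time series with
#' a size-3 uniform temporal filter; (2) compute `max(dF)`, the range of the
#' smoothed trace (maximum fluorescence change over its baseline); (3) divide
#' by `sigma(F)`, the standard deviation of the *unfiltered* trace; (4)
#' multiply the map by 1024; (5) subtract `median(map) - 16` from every pixel
#' so the median lands at the target gray level; (6) truncate to
#' `[clip_min, clip_max]` = `[9, 150]`, where 9 is the camera dark value on
#' an 8-bit scale. Pixels whose unfiltered variance is zero are set to
#' `clip_min`.
#'
#' @param video An [lf_video()] (>= 3 frames).
#' @param temporal_filter_size Uniform filter width in frames (odd, default 3).
#' @param scale Multiplicative factor applied to the ratio map (default 1024).
#' @param target_median Gray level the map median is shifted to (default 16).
#' @param clip_min,clip_max Output truncation bounds (defaults 9 and 150).
#' @param baseline `"min"` (default): `max(dF)` is the range of the smoothed
#'   trace, i.e. the maximum excursion above the trace minimum;
#'   `"percentile"`: excursion above the `baseline_percentile` quantile of the
#'   smoothed trace.
#' @param baseline_percentile Percentile (0-100) used when
#'   `baseline = "percentile"`.
#' @return A [light_field()] of rounded 8-bit values in
#'   `[clip_min, clip_max]`, with `dark_level = clip_min`.
#' @export
compute_activity_map <- function(video, temporal_filter_size = 3L,
                                 scale = 1024, target_median = 16,
                                 clip_min = 9, clip_max = 150,
                                 baseline = c("min", "percentile"),
                                 baseline_percentile = 10) {
  baseline <- match.arg(baseline)
  if (!(clip_min < target_median && target_median < clip_max))
    stop("need clip_min < target_median < clip_max", call. = FALSE)
  if (temporal_filter_size %% 2L == 0L)
    stop("`temporal_filter_size` must be odd", call. = FALSE)
  Fm <- video_matrix(video)                     # n_px x T
  n_t <- ncol(Fm)
  if (n_t < 3L) stop("activity map needs at least 3 frames", call. = FALSE)

  Sm <- as.matrix(Fm %*% Matrix::t(uniform_filter_matrix(n_t, temporal_filter_size)))
  base <- if (baseline == "min") {
    apply(Sm, 1L, min)
  } else {
    apply(Sm, 1L, stats::quantile, probs = baseline_percentile / 100,
          names = FALSE)
  }
  max_df <- apply(Sm, 1L, max) - base

  mu <- rowMeans(Fm)
  sigma <- sqrt(pmax(rowSums((Fm - mu)^2) / (n_t - 1L), 0))
  ok <- sigma > 0
  if (!any(ok))
    warning("all pixels are constant over time; activity map is uniform at clip_min")

  map <- numeric(nrow(Fm))
  map[ok] <- max_df[ok] / sigma[ok]
  map <- map * scale
  med <- stats::median(map[ok])
  if (!any(ok)) med <- target_median
  map <- map - (med - target_median)
  map[!ok] <- clip_min
  map <- pmin(pmax(map, clip_min), clip_max)
  d <- dim(if (inherits(video, "lf_video")) video$frames else video)
  light_field(matrix(round(map), d[1], d[2]), bit_depth = 8,
              dark_level = clip_min)
}
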