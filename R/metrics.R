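#' Trace signal-to-noise ratio in dB
#'
#' The trace is z-scored, then smoothed with a size-`smooth_size` uniform
#' filter (reflect boundary). Noise `N` is the standard deviation of the
#' difference between smoothed and unfiltered z-scored traces; signal `S` is
#' the range (max minus min) of the smoothed trace; the result is
#' `10 * log10(S / N)`. Because of the z-scoring the value is invariant to
#' affine transforms of the raw trace.
#'
#' @param trace Numeric vector, nonconstant, longer than `smooth_size`.
#' @param smooth_size Uniform filter width in samples (default 10).
#' @return SNR in dB.
#' @export
snr_db <- function(trace, smooth_size = 10L) {
  if (length(trace) <= smooth_size)
    stop("trace must be longer than the smoothing window", call. = FALSE)
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0)
    stop("SNR is undefined for a constant trace", call. = FALSE)
  z <- (trace - mean(trace)) / s
  sm <- uniform_filter1(z, smooth_size)
  n <- stats::sd(z - sm)
   10 * log10((max(sm) - min(sm)) / n)
}

#' Keep traces above an SNR floor
#'
#' Retains traces whose [snr_db()] is strictly greater than `floor_db`; the
#' standard 6 dB floor excludes obvious false-positive time series that are
#' dominated by noise.
#'
#' @param ts A [trace_set()].
#' @param floor_db Inclusion threshold in dB (strict `>`).
#' @param smooth_size Passed to [snr_db()].
#' @return A [trace_set()] restricted to the passing traces, with attribute
#'   `snr_db` (their SNRs) and `kept` (their original indices).
#' @export
filter_by_snr <- function(ts, floor_db = 6, smooth_size = 10L) {
  snrs <- apply(ts$S, 1L, snr_db, smooth_size = smooth_size)
  keep <- which(snrs > floor_db)
  out <- ts
  out$S <- ts$S[keep, , drop = FALSE]
  if (!is.null(ts$centroids_um))
    out$centroids_um <- ts$centroids_um[keep, , drop = FALSE]
  attr(out, "snr_db") <- snrs[keep]
  attr(out, "kept") <- keep
  out
}

#' Match traces across two extraction methods
#'
#' Greedy one-to-one pairing of two trace sets: candidate pairs with centroid
#' distance below `max_dist_um` are taken in order of increasing distance
#' (each trace used at most once), and a pair is retained only if the Pearson
#' correlation of its traces exceeds `min_corr`.
#'
#' @param a,b [trace_set()] objects with centroids and equal frame rates.
#' @param max_dist_um Centroid distance gate (um, strict `<`; default 20).
#' @param min_corr Correlation gate (strict `>`; default 0.5).
#' @return Data frame with columns `i`, `j` (row indices into `a` and `b`),
#'   `dist_um`, `r`.
#' @export
match_traces <- function(a, b, max_dist_um = 20, min_corr = 0.5) {
  if (!isTRUE(all.equal(a$frame_rate_hz, b$frame_rate_hz)))
    stop("frame rates differ between trace sets", call. = FALSE)
  if (is.null(a$centroids_um) || is.null(b$centroids_um))
    stop("both trace sets need centroids", call. = FALSE)
  na <- nrow(a$S); nb <- nrow(b$S)
  dd <- outer(seq_len(na), seq_len(nb), function(i, j) {
    sqrt(rowSums((a$centroids_um[i, , drop = FALSE] -
                    b$centroids_um[j, , drop = FALSE])^2))
  })
  cand <- which(dd < max_dist_um, arr.ind = TRUE)
  res <- data.frame(i = integer(0), j = integer(0), dist_um = numeric(0),
                    r = numeric(0))
  if (!nrow(cand)) return(res)
  cand <- cand[order(dd[cand]), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    r <- stats::cor(a$S[i, ], b$S[j, ])
    if (is.finite(r) && r > min_corr) {
      res <- rbind(res, data.frame(i = i, j = j, dist_um = dd[i, j], r = r))
    }
  }
  res
}

#' Correlation of neighboring traces (optical crosstalk surface)
#'
#' Tabulates every unordered trace pair whose centroids are within
#' `max_dist_um` (Euclidean), reporting the pair distance, the mean pair
#' depth, and the Pearson correlation of the raw traces. Spatially close,
#' highly correlated pairs indicate optical crosstalk (or true shared
#' activity).
#'
#' @param ts A [trace_set()] with centroids (>= 2 traces).
#' @param max_dist_um Neighbor gate in um (inclusive; default 50).
#' @return Data frame with columns `i`, `j`, `dist_um`, `mean_depth_um`, `r`.
#' @export
neighbor_crosstalk <- function(ts, max_dist_um = 50) {
  n <- nrow(ts$S)
  if (n < 2L) stop("need at least two traces", call. = FALSE)
  if (is.null(ts$centroids_um)) stop("trace set has no centroids", call. = FALSE)
  pairs <- utils::combn(n, 2L)
  d <- sqrt(colSums((t(ts$centroids_um)[, pairs[1, ], drop = FALSE] -
                       t(ts$centroids_um)[, pairs[2, ], drop = FALSE])^2))
  keep <- d <= max_dist_um
  i <- pairs[1, keep]; j <- pairs[2, keep]
  r <- vapply(seq_along(i),
              function(k) stats::cor(ts$S[i[k], ], ts$S[j[k], ]), numeric(1))
  data.frame(i = i, j = j, dist_um = d[keep],
             mean_depth_um = (ts$centroids_um[i, 3] + ts$centroids_um[j, 3]) / 2,
             r = r)
}

#' Downsample a trace by block averaging
#'
#' Non-overlapping means of `factor` adjacent samples. Averaging boosts the
#' SNR of white noise by the square root of the factor while reducing the
#' temporal resolution by the same factor.
#'
#' @param trace Numeric vector.
#' @param factor Integer >= 1; must not exceed the trace length.
#' @return Numeric vector of length `floor(length(trace) / factor)`.
#' @export
downsample_average <- function(trace, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor > length(trace))
    stop("`factor` exceeds the trace length", call. = FALSE)
  if (factor == 1L) return(trace)
  n <- (length(trace) %/% factor) * factor
  colMeans(matrix(trace[seq_len(n)], factor))
}
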