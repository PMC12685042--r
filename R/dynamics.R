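#' AR(1) nonnegative spike deconvolution (OASIS)
#'
#' Solves `min_c 0.5 ||c - y||^2 + lambda * sum(s)` subject to
#' `s(t) = c(t) - gamma c(t-1) >= 0` (with `c(0) = 0`) by the online
#' pool-adjacent-violators scheme: samples start as singleton pools, and a
#' pool whose start value undercuts the exponential continuation of its
#' predecessor is merged, in one backward sweep per sample. The sparsity
#' penalty enters as the usual shift of the target trace. The fitted calcium
#' obeys the AR(1) recursion `c(t) = gamma c(t-1) + s(t)` exactly.
#'
#' @param y Numeric trace (fluorescence, arbitrary units).
#' @param gamma AR(1) decay per frame, in (0, 1). A natural default for an
#'   indicator with decay time constant `tau` sampled at `f` Hz is
#'   `exp(-1 / (f * tau))`.
#' @param lambda Nonnegative sparsity penalty.
#' @return A `deconv_result`: list with `denoised` (fitted calcium `c`),
#'   `spikes` (inferred activity `s`), `gamma`, `lambda`.
#' @export
oasis_ar1 <- function(y, gamma, lambda = 0) {
  if (!(gamma > 0 && gamma < 1))
    stop("`gamma` must lie strictly inside (0, 1)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  n <- length(y)
  if (n < 1L) stop("empty trace", call. = FALSE)
  # sparsity penalty as a shift of the target
  yt <- y - lambda * (1 - gamma)
  yt[n] <- y[n] - lambda

  v <- numeric(n); w <- numeric(n); t0 <- integer(n); len <- integer(n)
  np <- 0L
  for (t in seq_len(n)) {
    np <- np + 1L
    v[np] <- yt[t]; w[np] <- 1; t0[np] <- t; len[np] <- 1L
    while (np > 1L && v[np] < gamma^len[np - 1L] * v[np - 1L]) {
      g <- gamma^len[np - 1L]
      wn <- w[np - 1L] + g^2 * w[np]
      v[np - 1L] <- (w[np - 1L] * v[np - 1L] + g * w[np] * v[np]) / wn
      w[np - 1L] <- wn
      len[np - 1L] <- len[np - 1L] + len[np]
      np <- np - 1L
    }
  }
  cfit <- numeric(n)
  for (p in seq_len(np)) {
    val <- max(v[p], 0)
    cfit[t0[p]:(t0[p] + len[p] - 1L)] <- val * gamma^(0:(len[p] - 1L))
  }
  s <- c(cfit[1], cfit[-1] - gamma * cfit[-n])
  s[s < 0 & s > -1e-12] <- 0
  structure(list(denoised = cfit, spikes = s, gamma = gamma, lambda = lambda),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d frames, gamma %.4g, lambda %.4g, %d active bins\n",
              length(x$denoised), x$gamma, x$lambda, sum(x$spikes > 0)))
  invisible(x)
}

#' Putative spike times from a deconvolved activity trace
#'
#' Detections are the local maxima of the inferred activity `s` whose
#' amplitude exceeds `min_amplitude_frac * max(s)`. Because a finite
#' indicator rise time spreads the inferred activity of one spike over the
#' rising-phase frames (the AR(1) model assumes an instantaneous rise), each
#' detection is reported at the onset of its contiguous run of positive
#' activity -- the first frame the event touches -- rather than at the peak
#' itself; peaks sharing one run collapse to a single detection. Set
#' `refine_onset = FALSE` to report raw peak frames.
#'
#' @param s Nonnegative activity vector (e.g. `oasis_ar1()$spikes`).
#' @param min_amplitude_frac Detection threshold as a fraction of the peak
#'   activity (default 0.1).
#' @param refine_onset Report run onsets instead of peak frames (default
#'   `TRUE`).
#' @return Integer vector of frame indices (sorted, unique).
#' @export
detect_putative_spikes <- function(s, min_amplitude_frac = 0.1,
                                   refine_onset = TRUE) {
  if (min(s) < 0) stop("activity must be nonnegative", call. = FALSE)
  mx <- max(s)
  if (mx == 0) return(integer(0))
  n <- length(s)
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  peaks <- which(s >= left & s >= right & s > min_amplitude_frac * mx)
  if (!refine_onset || !length(peaks)) return(peaks)
  onsets <- vapply(peaks, function(p) {
    while (p > 1L && s[p - 1L] > 0 && s[p - 1L] < s[p]) p <- p - 1L
    p
  }, integer(1))
  sort(unique(onsets))
}

#' Cluster deconvolved traces into putative ensembles
#'
#' Agglomerative hierarchical clustering (average linkage) on the correlation
#' distance `1 - r` between deconvolved calcium traces. The number of
#' clusters follows the detected-population rule: about six time series per
#' cluster, `k = max(1, round(n / 6))`.
#'
#' @param ts A [trace_set()] (or plain matrix, traces in rows).
#' @param traces_per_cluster Average cluster occupancy target (default 6).
#' @param linkage `stats::hclust` method (default `"average"`).
#' @return A `cluster_result`: `labels` (per-trace cluster id), `n_clusters`,
#'   `linkage`, `order` (dendrogram order), `hclust` (the tree).
#' @export
cluster_traces <- function(ts, traces_per_cluster = 6, linkage = "average") {
  S <- if (inherits(ts, "trace_set")) ts$S else as.matrix(ts)
  n <- nrow(S)
  if (n < 2L) {
    return(structure(list(labels = rep(1L, n), n_clusters = 1L,
                          linkage = linkage, order = seq_len(n),
                          hclust = NULL),
                     class = "cluster_result"))
  }
  cm <- stats::cor(t(S))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = linkage)
  k <- max(1L, as.integer(round(n / traces_per_cluster)))
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, n_clusters = k, linkage = linkage,
                 order = hc$order, hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d traces in %d clusters (%s linkage)\n",
              length(x$labels), x$n_clusters, x$linkage))
  invisible(x)
}

#' Within- versus between-cluster distance statistics
#'
#' Compares the Euclidean distances between cell centroids within a cluster
#' against distances between cells of different clusters, with two-sided
#' Mann-Whitney U and independent-samples t tests. Spatially intermingled
#' ensembles yield indistinguishable distributions (large p-values).
#'
#' @param clusters A [cluster_traces()] result (or integer label vector).
#' @param centroids_um `n x 3` matrix of cell centroids (um).
#' @return List with `intra_distances`, `inter_distances`, `medians`, `iqrs`,
#'   `mann_whitney_p`, `t_test_p`.
#' @export
intra_inter_distance_test <- function(clusters, centroids_um) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  n <- length(labels)
  if (nrow(centroids_um) != n)
    stop("centroid count must match the number of labeled traces", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need at least two clusters to compare within vs between", call. = FALSE)
  pr <- utils::combn(n, 2L)
  d <- sqrt(colSums((t(centroids_um)[, pr[1, ], drop = FALSE] -
                       t(centroids_um)[, pr[2, ], drop = FALSE])^2))
  same <- labels[pr[1, ]] == labels[pr[2, ]]
  intra <- d[same]; inter <- d[!same]
  if (!length(intra) || !length(inter))
    stop("degenerate clustering: empty within- or between-cluster set", call. = FALSE)
  list(intra_distances = intra,
       inter_distances = inter,
       medians = c(intra = stats::median(intra), inter = stats::median(inter)),
       iqrs = c(intra = stats::IQR(intra), inter = stats::IQR(inter)),
       mann_whitney_p = stats::wilcox.test(intra, inter, exact = FALSE)$p.value,
       t_test_p = stats::t.test(intra, inter)$p.value)
}
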