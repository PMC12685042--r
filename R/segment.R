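#' ROI label volume
#'
#' Integer-labeled 3D grid (0 = background) with per-ROI voxel counts and
#' voxel-space centroids. Labels are contiguous `1..n_rois` and each label is
#' one connected component.
#'
#' @param labels Integer 3D array.
#' @param config Optional [lfm_config()] sharing the grid.
#' @return A `label_volume`.
#' @export
label_volume <- function(labels, config = NULL) {
  stopifnot(length(dim(labels)) == 3L)
  ids <- sort(unique(labels[labels > 0]))
  # compact to 1..n
  lab <- array(0L, dim(labels))
  lab[labels > 0] <- match(labels[labels > 0], ids)
  n <- length(ids)
  counts <- if (n) tabulate(lab[lab > 0], n) else integer(0)
  cent <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("y", "x", "z")))
  if (n) {
    idx <- which(lab > 0)
    d <- dim(lab)
    iy <- ((idx - 1L) %% d[1]) + 1L
    ix <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
    iz <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    g <- lab[idx]
    cent[, 1] <- tapply(iy, g, mean)
    cent[, 2] <- tapply(ix, g, mean)
    cent[, 3] <- tapply(iz, g, mean)
  }
  structure(list(labels = lab, n_rois = n, voxel_counts = counts,
                 centroids_vox = cent, config = config),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d ROIs over %s voxels\n", x$n_rois,
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

# Otsu's threshold on a 256-bin histogram; returns the bin-edge value
# maximizing between-class variance (first maximum on ties).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, -Inf)
  br[which.max(bcv) + 1L]
}

#' Voronoi-Otsu labeling of a 3D volume
#'
#' Segments bright blobs (somata) in a reconstructed activity volume:
#' \enumerate{
#'   \item blur with `sigma_spot` and detect 26-connected local maxima as
#'     seeds (plateaus collapse to the voxel with the lowest linear index);
#'   \item blur with `sigma_outline` and threshold with Otsu's method (256
#'     bins) to obtain the foreground mask;
#'   \item discard seeds outside the mask, then assign every foreground voxel
#'     to its nearest seed (Euclidean distance in voxel units).
#' }
#' With `peak_frac > 0`, each Voronoi cell is additionally trimmed to the
#' voxels whose (unblurred) intensity reaches that fraction of the cell's
#' peak, which tightens ROIs around the soma core and sharpens their
#' unweighted centroids. Each label is finally reduced to the connected
#' component containing its brightest voxel, so labels are guaranteed
#' connected. A constant volume yields zero ROIs.
#'
#' @param v An [lfm_volume()] or 3D array, nonnegative.
#' @param sigma_spot Gaussian sigma (voxels) for seed detection; scalar or
#'   length-3 `(y, x, z)`. Default 3.
#' @param sigma_outline Gaussian sigma (voxels) for the outline mask.
#'   Default 1.
#' @param min_voxels Discard ROIs smaller than this many voxels (default 0).
#' @param peak_frac Per-ROI core threshold as a fraction of the ROI's peak
#'   intensity (default 0 = off).
#' @return A [label_volume()].
#' @export
voronoi_otsu_label <- function(v, sigma_spot = 3, sigma_outline = 1,
                               min_voxels = 0L, peak_frac = 0) {
  cfg <- if (inherits(v, "lfm_volume")) v$config else NULL
  a <- as_volume_array(v)
  if (min(a) < 0) stop("volume must be nonnegative", call. = FALSE)
  d <- dim(a)
  if (max(a) == min(a)) {
    return(label_volume(array(0L, d), config = cfg))
  }
  spot <- gauss_blur_3d(a, sigma_spot)
  outl <- gauss_blur_3d(a, sigma_outline)
  thr <- otsu_threshold(as.vector(outl))
  mask <- outl > thr

  cand <- local_maxima_3d(spot) & mask
  if (!any(cand)) return(label_volume(array(0L, d), config = cfg))
  # collapse plateaus: equal-valued, 26-connected candidate groups -> one seed
  plat <- connected_components_3d(cand, connectivity = 26L, values = spot)
  n_seed <- max(plat)
  seed_idx <- vapply(seq_len(n_seed),
                     function(g) min(which(plat == g)), integer(1))

  # nearest-seed (Voronoi) assignment of foreground voxels, voxel metric
  fg <- which(mask)
  to_yxz <- function(idx) {
    cbind(((idx - 1L) %% d[1]) + 1L,
          ((idx - 1L) %/% d[1]) %% d[2] + 1L,
          ((idx - 1L) %/% (d[1] * d[2])) + 1L)
  }
  fgc <- to_yxz(fg)
  sc <- to_yxz(seed_idx)
  assign <- integer(length(fg))
  bestd <- rep(Inf, length(fg))
  for (gi in seq_len(n_seed)) {
    dd <- (fgc[, 1] - sc[gi, 1])^2 + (fgc[, 2] - sc[gi, 2])^2 +
      (fgc[, 3] - sc[gi, 3])^2
    upd <- dd < bestd
    assign[upd] <- gi
    bestd[upd] <- dd[upd]
  }
  lab <- array(0L, d)
  lab[fg] <- assign

  if (peak_frac > 0) {
    for (gi in seq_len(n_seed)) {
      sel <- lab == gi
      if (any(sel)) lab[sel & a < peak_frac * max(a[sel])] <- 0L
    }
  }

  # keep only the connected component of each label containing its brightest
  # voxel (the seed itself may fall outside a trimmed core)
  for (gi in seq_len(n_seed)) {
    sel <- lab == gi
    if (!any(sel)) next
    comp <- connected_components_3d(sel, connectivity = 6L)
    anchor <- which(sel)[which.max(a[sel])]
    keep <- comp[anchor]
    lab[sel & comp != keep] <- 0L
  }
  if (min_voxels > 0L) {
    cnt <- tabulate(lab[lab > 0L], n_seed)
    drop <- which(cnt < min_voxels)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  label_volume(lab, config = cfg)
}

#' Physical ROI centroids
#'
#' Intensity-unweighted voxel centroids of a [label_volume()], converted to
#' micrometers: lateral coordinates are `(index - 0.5) * lateral_voxel_um`
#' from the volume corner, and `z` is the signed depth relative to the native
#' focal plane.
#'
#' @param labels A [label_volume()].
#' @param config An [lfm_config()]; defaults to the one stored in `labels`.
#' @return `n_rois x 3` matrix with columns `y_um`, `x_um`, `z_um`.
#' @export
roi_centroids_um <- function(labels, config = labels$config) {
  if (is.null(config)) stop("no configuration available for unit conversion",
                            call. = FALSE)
  vl <- lateral_voxel_um(config)
  zz <- z_depths_um(config)
  cent <- labels$centroids_vox
  out <- cbind(y_um = (cent[, 1] - 0.5) * vl,
               x_um = (cent[, 2] - 0.5) * vl,
               z_um = zz[1] + (cent[, 3] - 1) * config$z_step_um)
  out
}
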