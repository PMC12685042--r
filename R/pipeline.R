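#' Run the full calcium extraction pipeline
#'
#' Chains all stages on a light-field video: activity map, sparse (or RL)
#' reconstruction of the activity volume, Voronoi-Otsu segmentation,
#' footprint demixing (matrix method) and optionally per-frame reconstruction
#' with ROI averaging, SNR filtering, neighbor-crosstalk tabulation, AR(1)
#' deconvolution and ensemble clustering. When no video is supplied, a
#' synthetic scenario is generated so the pipeline is runnable end to end out
#' of the box.
#'
#' @param video An [lf_video()], or `NULL` to simulate one.
#' @param config The [lfm_config()]; defaults to [demo_lfm_config()].
#' @param bank Optional pre-built [build_psf_bank()].
#' @param gt Optional [simulate_ground_truth()] used when `video` is `NULL`
#'   (one is generated from `seed` otherwise).
#' @param method Reconstruction for the activity volume: `"rl"` (default),
#'   `"ista"` or `"fista"`.
#' @param n_iter Iterations for the activity-volume reconstruction.
#' @param lambda_rel Sparsity weight relative to `max(A' l)` for the sparse
#'   solvers.
#' @param roi_traces Also reconstruct every frame and extract ROI-mean traces
#'   (slower; default `FALSE`).
#' @param min_voxels Minimum ROI size in voxels kept by segmentation.
#' @param peak_frac Per-ROI core threshold passed to [voronoi_otsu_label()].
#' @param snr_floor_db Trace inclusion threshold (default 6).
#' @param seed Master seed recorded in the manifest.
#' @param out_dir Directory for output files (`NULL` = no files written).
#' @return A list bundle: `activity_map`, `activity_volume`, `labels`,
#'   `footprints`, `traces` (matrix method, SNR-filtered), `traces_all`,
#'   `snr_db`, `crosstalk`, `deconvolution`, `clusters`, `manifest`,
#'   and `gt` when simulated.
#' @export
run_pipeline <- function(video = NULL, config = demo_lfm_config(),
                         bank = NULL, gt = NULL,
                         method = c("rl", "ista", "fista"),
                         n_iter = if (method == "rl") 8L else 150L,
                         lambda_rel = 0.02, roi_traces = FALSE,
                         min_voxels = 8L, peak_frac = 0.3,
                         snr_floor_db = 6, seed = 1L, out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(bank)) bank <- build_psf_bank(config)
  simulated <- is.null(video)
  if (simulated) {
    if (is.null(gt)) gt <- simulate_ground_truth(config, seed = seed)
    video <- render_lf_video(gt, bank, seed = seed)
  }

  amap <- compute_activity_map(video)
  l0 <- pmax(amap$data - amap$dark_level, 0)
  avol <- if (method == "rl") {
    richardson_lucy(light_field(l0), bank, n_iter = n_iter)
  } else {
    lam <- lambda_rel * max(as.numeric(Matrix::crossprod(forward_operator(bank),
                                                         as.vector(l0))))
    ista_reconstruct(light_field(l0), bank, n_iter = n_iter, lambda = lam,
                     method = method)
  }

  vl <- lateral_voxel_um(config)
  sig_spot <- c(3, 3, 3 * vl / config$z_step_um)      # isotropic in um
  sig_out <- c(1, 1, max(vl / config$z_step_um, 0.25))
  labels <- voronoi_otsu_label(avol, sigma_spot = sig_spot,
                               sigma_outline = sig_out,
                               min_voxels = min_voxels,
                               peak_frac = peak_frac)
  if (labels$n_rois < 1L)
    stop("pipeline stage `segment`: no ROIs found in the activity volume",
         call. = FALSE)

  fp <- build_footprint_matrix(labels, bank)
  traces_all <- extract_matrix_traces(fp, video)
  traces <- filter_by_snr(traces_all, floor_db = snr_floor_db)

  roi_ts <- NULL
  if (roi_traces) {
    Vs <- reconstruct_video(video, bank, method = method,
                            lambda = if (method == "rl") 0 else
                              lambda_rel * max(fp$Y))
    roi_ts <- extract_roi_traces(Vs, labels,
                                 frame_rate_hz = video$frame_rate_hz)
  }

  ct <- if (nrow(traces$S) >= 2L) neighbor_crosstalk(traces) else NULL

  gamma <- exp(-1 / (video$frame_rate_hz * 0.15))
  dec <- lapply(seq_len(nrow(traces$S)), function(i) {
    y <- traces$S[i, ]
    oasis_ar1(y - stats::quantile(y, 0.1, names = FALSE), gamma,
              lambda = 0.1 * stats::mad(diff(y)))
  })
  clusters <- if (nrow(traces$S) >= 2L) {
    cluster_traces(do.call(rbind, lapply(dec, `[[`, "denoised")))
  } else NULL

  manifest <- list(seed = seed, method = method, n_iter = n_iter,
                   lambda_rel = lambda_rel, snr_floor_db = snr_floor_db,
                   config_hash = config_hash(config),
                   n_rois = labels$n_rois, n_traces_kept = nrow(traces$S),
                   package_version = as.character(utils::packageVersion("lfcalcium")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_light_field(amap, file.path(out_dir, "activity_map.tif"))
    write_label_volume(labels, file.path(out_dir, "labels.tif"))
    write_traces_csv(traces_all, file.path(out_dir, "traces_matrix.csv"))
    if (!is.null(roi_ts))
      write_traces_csv(roi_ts, file.path(out_dir, "traces_roi.csv"))
    snr_all <- apply(traces_all$S, 1L, snr_db)
    utils::write.csv(data.frame(roi = seq_along(snr_all), snr_db = snr_all,
                                kept = seq_along(snr_all) %in% attr(traces, "kept")),
                     file.path(out_dir, "qc.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  out <- list(activity_map = amap, activity_volume = avol, labels = labels,
              footprints = fp, traces = traces, traces_all = traces_all,
              roi_traces = roi_ts, crosstalk = ct, deconvolution = dec,
              clusters = clusters, manifest = manifest)
  if (simulated) out$gt <- gt
  out
}
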