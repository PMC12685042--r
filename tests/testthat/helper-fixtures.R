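# Shared fixtures. Heavy objects are built once per test run and memoised in
# this environment.

.fixtures <- new.env(parent = emptyenv())

# 5x5-lenslet configuration used for dense-operator oracles.
tiny_config <- function() {
  lfm_config(n_lenslets_y = 5, n_lenslets_x = 5, pixels_per_lenslet = 5,
             n_z = 5, z_step_um = 8, lateral_supersampling = 1)
}

tiny_bank <- function() {
  if (is.null(.fixtures$tiny_bank)) .fixtures$tiny_bank <- build_psf_bank(tiny_config())
  .fixtures$tiny_bank
}

# Mid-size configuration for reconstruction tests.
mid_config <- function() {
  lfm_config(n_lenslets_y = 9, n_lenslets_x = 9, pixels_per_lenslet = 5,
             n_z = 5, z_step_um = 6, lateral_supersampling = 1)
}

mid_bank <- function() {
  if (is.null(.fixtures$mid_bank)) .fixtures$mid_bank <- build_psf_bank(mid_config())
  .fixtures$mid_bank
}

# Brute-force projector: independent of the sparse-operator code path; places
# each voxel's kernel on the sensor by explicit shifting and clipping.
naive_forward <- function(varr, bank) {
  cfg <- bank$config
  s <- cfg$lateral_supersampling
  ppl <- cfg$pixels_per_lenslet
  sd2 <- sensor_dim(cfg)
  out <- matrix(0, sd2[1], sd2[2])
  idx <- which(varr != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    y <- idx[r, 1]; x <- idx[r, 2]; k <- idx[r, 3]
    ly <- (y - 1L) %/% s + 1L; py <- (y - 1L) %% s
    lx <- (x - 1L) %/% s + 1L; px <- (x - 1L) %% s
    ker <- bank$kernels[[k]][[py * s + px + 1L]]
    m <- ker$m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] == 0) next
      sr <- (ly - 1L) * ppl + ker$o + i
      sc <- (lx - 1L) * ppl + ker$o + j
      if (sr >= 1 && sr <= sd2[1] && sc >= 1 && sc <= sd2[2])
        out[sr, sc] <- out[sr, sc] + varr[y, x, k] * m[i, j]
    }
  }
  out
}

# Greedy one-to-one matching of detected vs true centers within a radius.
greedy_center_match <- function(detected, truth, radius_um) {
  nd <- nrow(detected); nt <- nrow(truth)
  D <- as.matrix(stats::dist(rbind(detected, truth)))[seq_len(nd),
                                                      nd + seq_len(nt),
                                                      drop = FALSE]
  ord <- order(D)
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- NULL
  for (k in ord) {
    if (D[k] >= radius_um) break
    i <- (k - 1) %% nd + 1; j <- (k - 1) %/% nd + 1
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  list(pairs = pairs, tp = sum(used_t),
       f1 = 2 * sum(used_t) / (nd + nt))
}

# Fraction of true spikes with a detection within `tol` frames; spike times
# are aligned to the first frame they can affect.
spike_recall <- function(det_frames, spike_times, frame_rate, tol = 1) {
  if (!length(spike_times)) return(NA_real_)
  tf <- floor(spike_times * frame_rate) + 2
  mean(vapply(tf, function(t) any(abs(det_frames - t) <= tol), logical(1)))
}

# The full synthetic study scenario (heavy): generated once per run.
study_scenario <- function(seed = 1L) {
  key <- paste0("study_", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- demo_lfm_config()
    if (is.null(.fixtures$demo_bank)) .fixtures$demo_bank <- build_psf_bank(cfg)
    bank <- .fixtures$demo_bank
    gt <- simulate_ground_truth(cfg, seed = seed)
    res <- run_pipeline(config = cfg, bank = bank, gt = gt, seed = seed)
    .fixtures[[key]] <- list(cfg = cfg, bank = bank, gt = gt, res = res)
  }
  .fixtures[[key]]
}

demo_bank <- function() {
  if (is.null(.fixtures$demo_bank))
    .fixtures$demo_bank <- build_psf_bank(demo_lfm_config())
  .fixtures$demo_bank
}

# Lawson-Hanson active-set NNLS: independent oracle for the lambda = 0
# sparse solver (projected least squares).
nnls_lawson_hanson <- function(A, b, tol = 1e-10, max_iter = 300L) {
  n <- ncol(A)
  P <- logical(n)
  x <- numeric(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  it <- 0L
  while (any(!P) && max(w[!P]) > tol && it < max_iter) {
    it <- it + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- as.numeric(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[P] > tol)) break
      alpha <- min(x[P] / (x[P] - s[P]), na.rm = TRUE)
      idx <- which(P)[s[P] <= tol]
      alpha <- min(x[idx] / (x[idx] - s[idx]))
      x <- x + alpha * (s - x)
      P[x <= tol & P] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}
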