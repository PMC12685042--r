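test_that("closed-form optics calculators reproduce the instrument values", {
  cfg <- lfm_config()  # reference instrument defaults
  expect_equal(native_lateral_resolution(cfg), 5)
  expect_equal(resolvable_spots_per_lenslet(cfg, spot_size_um = 6.2), 19L)
  expect_equal(snr_penalty_per_doubling(), 10 * log10(sqrt(2)), tolerance = 1e-12)
  expect_equal(snr_penalty_per_doubling(2), 1.505, tolerance = 1e-3)
  expect_equal(axial_span_um(cfg), 104)

  # trivial ratio identities
  expect_equal(native_lateral_resolution(lfm_config(magnification = 1)), 125)
  expect_equal(native_lateral_resolution(
    lfm_config(lenslet_pitch_um = 100, magnification = 20)), 5)
  expect_equal(resolvable_spots_per_lenslet(cfg, spot_size_um = 125), 1L)
  expect_equal(resolvable_spots_per_lenslet(
    lfm_config(lenslet_pitch_um = 120, camera_pixel_um = 6), 5), 20L)
  expect_equal(snr_penalty_per_doubling(1), 0)
  expect_equal(snr_penalty_per_doubling(4), 2 * snr_penalty_per_doubling(2))
})

test_that("configuration validation rejects inconsistent geometry", {
  expect_error(lfm_config(magnification = 0), "magnification")
  expect_error(lfm_config(magnification = -2), "magnification")
  expect_error(lfm_config(pixels_per_lenslet = 4), "odd")
  expect_error(lfm_config(pixels_per_lenslet = 1), "odd")
  expect_error(lfm_config(n_z = 6), "odd")
  expect_error(lfm_config(lenslet_pitch_um = -1), "positive")
  expect_error(resolvable_spots_per_lenslet(lfm_config(), spot_size_um = 0),
               "spot_size")
  # sensor and volume sizes follow the lenslet grid exactly
  cfg <- tiny_config()
  expect_identical(sensor_dim(cfg), c(25L, 25L))
  expect_identical(volume_dim(cfg), c(5L, 5L, 5L))
  expect_equal(z_depths_um(cfg), c(-16, -8, 0, 8, 16))
})

test_that("configurations round-trip through YAML", {
  cfg <- demo_lfm_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lfm_config(cfg, path)
  cfg2 <- read_lfm_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})

test_that("PSF kernels are nonnegative, unit-sum, and in-focus energy stays in the source lenslet", {
  bank <- tiny_bank()
  ppl <- 5L
  for (k in seq_along(bank$kernels)) {
    for (ph in seq_along(bank$kernels[[k]])) {
      ker <- bank$kernels[[k]][[ph]]
      expect_gte(min(ker$m), 0)
      expect_equal(sum(ker$m), 1, tolerance = 1e-9)
    }
  }
  # z = 0 kernel: > 80% of the energy within the source lenslet
  k0 <- bank$kernels[[3]][[1]]
  Lh <- -k0$o / ppl
  src <- (Lh * ppl + 1):(Lh * ppl + ppl)
  expect_gt(sum(k0$m[src, src]), 0.8)
})

test_that("per-depth kernel energy is identical across sub-lenslet phases", {
  cfg <- lfm_config(n_lenslets_y = 5, n_lenslets_x = 5, pixels_per_lenslet = 5,
                    n_z = 3, z_step_um = 8, lateral_supersampling = 3)
  bank <- build_psf_bank(cfg)
  for (k in 1:3) {
    sums <- vapply(bank$kernels[[k]], function(kk) sum(kk$m), numeric(1))
    expect_equal(max(sums) - min(sums), 0, tolerance = 1e-12)
  }
})

test_that("disparity: lenslet-space centroid at a fixed view angle moves monotonically with depth", {
  bank <- tiny_bank()
  ppl <- 5L
  cent <- vapply(seq_along(bank$z_um), function(k) {
    ker <- bank$kernels[[k]][[1]]
    m <- ker$m
    nl <- nrow(m) / ppl
    rows <- seq(4L, nrow(m), by = ppl)  # angular pixel (+1, 0) of each lenslet
    cols <- seq(3L, ncol(m), by = ppl)
    sub <- m[rows, cols]
    lens <- seq_len(nl) - (nl + 1) / 2
    sum(lens * rowSums(sub)) / sum(sub)
  }, numeric(1))
  expect_true(all(diff(cent) > 0))
})

test_that("unsupported PSF mode errors; fresnel mode builds valid kernels", {
  expect_error(build_psf_bank(tiny_config(), mode = "wave"), "arg")
  bank <- build_psf_bank(tiny_config(), mode = "fresnel")
  expect_equal(sum(bank$kernels[[1]][[1]]$m), 1, tolerance = 1e-9)
  expect_gte(min(bank$kernels[[1]][[1]]$m), 0)
})

test_that("forward operator equals the brute-force kernel projector entrywise", {
  bank <- tiny_bank()
  A <- forward_operator(bank)
  set.seed(11)
  vd <- volume_dim(bank$config)
  # every basis voxel of two z-planes plus random dense volumes
  for (k in c(1L, 3L)) {
    for (trial in 1:4) {
      v <- array(0, vd)
      v[sample(vd[1], 1), sample(vd[2], 1), k] <- 1
      expect_equal(forward_project(v, bank)$data, naive_forward(v, bank),
                   tolerance = 1e-12)
    }
  }
  for (trial in 1:3) {
    v <- array(runif(prod(vd)), vd)
    expect_equal(forward_project(v, bank)$data, naive_forward(v, bank),
                 tolerance = 1e-10)
  }
})

test_that("full dense materialization of the tiny operator matches basis projections", {
  bank <- tiny_bank()
  A <- as.matrix(forward_operator(bank))
  vd <- volume_dim(bank$config)
  set.seed(4)
  for (j in sample(prod(vd), 20)) {
    e <- array(0, vd); e[j] <- 1
    expect_equal(A[, j], as.vector(naive_forward(e, bank)), tolerance = 1e-12)
  }
})

test_that("forward and back projection are exact adjoints on 100 random pairs", {
  bank <- tiny_bank()
  set.seed(21)
  vd <- volume_dim(bank$config); sd2 <- sensor_dim(bank$config)
  worst <- 0
  for (i in 1:100) {
    v <- array(runif(prod(vd)), vd)
    l <- matrix(runif(prod(sd2)), sd2[1], sd2[2])
    Av <- forward_project(v, bank)$data
    Atl <- back_project(l, bank)$data
    err <- abs(sum(Av * l) - sum(v * Atl)) /
      (sqrt(sum(Av^2)) * sqrt(sum(l^2)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("projection is linear and conserves energy for interior sources", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  set.seed(5)
  v1 <- array(0, vd); v2 <- array(0, vd)
  v1[4:6, 4:6, 2:4] <- runif(27)
  v2[4:6, 4:6, 2:4] <- runif(27)
  lf1 <- forward_project(v1, bank)$data
  lf2 <- forward_project(v2, bank)$data
  lf12 <- forward_project(2 * v1 + 3 * v2, bank)$data
  expect_equal(lf12, 2 * lf1 + 3 * lf2, tolerance = 1e-12)
  expect_equal(sum(lf1), sum(v1), tolerance = 1e-6)
  # zero volume projects to zero; zero LF backprojects to zero
  expect_equal(max(abs(forward_project(array(0, vd), bank)$data)), 0)
  expect_equal(max(abs(back_project(matrix(0, 45, 45), bank)$data)), 0)
})

test_that("delta light field backprojects to the corresponding operator row", {
  bank <- tiny_bank()
  A <- forward_operator(bank)
  sd2 <- sensor_dim(bank$config)
  l <- matrix(0, sd2[1], sd2[2]); l[13, 12] <- 1
  pix <- 13 + (12 - 1) * sd2[1]
  expect_equal(as.vector(back_project(l, bank)$data),
               as.numeric(A[pix, ]), tolerance = 1e-12)
})

test_that("translating a source by one lenslet translates its footprint by one period", {
  bank <- tiny_bank()
  ppl <- 5L
  vd <- volume_dim(bank$config)
  v1 <- array(0, vd); v1[2, 2, 2] <- 1
  v2 <- array(0, vd); v2[3, 2, 2] <- 1  # +1 lenslet in y (supersampling 1)
  lf1 <- forward_project(v1, bank)$data
  lf2 <- forward_project(v2, bank)$data
  # compare on the interior rows where neither footprint is clipped
  rows <- (ppl + 1):(nrow(lf1) - ppl)
  expect_equal(lf2[rows, ], lf1[rows - ppl, ], tolerance = 1e-12)
})

test_that("shape mismatches raise errors", {
  bank <- tiny_bank()
  expect_error(forward_project(array(0, c(4, 5, 5)), bank), "shape")
  expect_error(back_project(matrix(0, 10, 25), bank), "shape")
})
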