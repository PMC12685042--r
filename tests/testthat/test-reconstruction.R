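test_that("Richardson-Lucy localizes a noiseless point source within one voxel", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  for (src in list(c(4, 6, 2), c(5, 5, 3), c(6, 4, 4))) {
    v0 <- array(0, vd); v0[src[1], src[2], src[3]] <- 1
    lf <- forward_project(v0, bank)
    rec <- richardson_lucy(lf, bank, n_iter = 8)
    am <- which(rec$data == max(rec$data), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(am - src)), 1)
  }
})

test_that("RL iterates stay nonnegative and conserve flux on interior phantoms", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  set.seed(8)
  v0 <- array(0, vd)
  v0[4:6, 4:6, 2:4] <- runif(27)
  lf <- forward_project(v0, bank)
  for (it in c(1, 4, 8)) {
    rec <- richardson_lucy(lf, bank, n_iter = it)
    expect_gte(min(rec$data), 0)
  }
  rec8 <- richardson_lucy(lf, bank, n_iter = 8)
  expect_lt(abs(sum(rec8$data) - sum(lf$data)) / sum(lf$data), 0.01)
  # zero light field with backprojection init stays zero/nonnegative
  z <- richardson_lucy(light_field(matrix(0, 45, 45)), bank, n_iter = 3)
  expect_equal(max(abs(z$data)), 0)
  expect_error(richardson_lucy(light_field(matrix(-1, 45, 45)), bank),
               "negative")
})

test_that("axial confinement of reconstructed sources does not worsen with RL iterations", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  v0 <- array(0, vd); v0[4, 4, 2] <- 1; v0[6, 6, 4] <- 1
  lf <- forward_project(v0, bank)
  axial_spread <- function(rec) {
    prof <- apply(rec$data, 3, sum)
    prof <- prof / sum(prof)
    ks <- seq_along(prof)
    sqrt(sum(prof * (ks - sum(prof * ks))^2))
  }
  s1 <- axial_spread(richardson_lucy(lf, bank, n_iter = 1))
  s8 <- axial_spread(richardson_lucy(lf, bank, n_iter = 8))
  expect_lte(s8, s1 + 1e-9)
})

test_that("ISTA objective is monotonically non-increasing and divergence is caught", {
  bank <- tiny_bank()
  set.seed(12)
  lf <- light_field(matrix(runif(625), 25, 25))
  rec <- ista_reconstruct(lf, bank, n_iter = 120, lambda = 0.05)
  ob <- attr(rec, "objectives")
  expect_true(all(diff(ob) <= 1e-9 * abs(ob[-length(ob)]) + 1e-12))
  # a step size above 2/L diverges and must trigger the guard
  expect_error(ista_reconstruct(lf, bank, n_iter = 50, lambda = 0,
                                nonneg = FALSE,
                                step = 2.5 / operator_lipschitz(bank)),
               "step size")
})

test_that("a large l1 weight collapses the ISTA solution to zero", {
  bank <- tiny_bank()
  set.seed(13)
  lf <- light_field(matrix(runif(625), 25, 25))
  lam_max <- max(abs(back_project(lf, bank)$data))
  rec <- ista_reconstruct(lf, bank, n_iter = 30, lambda = 1.01 * lam_max)
  expect_equal(max(abs(rec$data)), 0)
})

test_that("lambda = 0 ISTA matches the Lawson-Hanson NNLS oracle", {
  bank <- tiny_bank()
  A <- as.matrix(forward_operator(bank))
  vd <- volume_dim(bank$config)
  set.seed(14)
  v_true <- array(0, vd)
  v_true[sample(length(v_true), 10)] <- runif(10, 0.5, 2)
  b <- as.numeric(A %*% as.vector(v_true)) + abs(rnorm(nrow(A), 0, 0.01))
  x_oracle <- nnls_lawson_hanson(A, b)
  rec <- ista_reconstruct(light_field(matrix(b, 25, 25)), bank,
                          n_iter = 2000, lambda = 0, method = "fista")
  err <- sqrt(sum((as.vector(rec$data) - x_oracle)^2)) /
    max(sqrt(sum(x_oracle^2)), 1e-12)
  expect_lt(err, 1e-4)
})

test_that("FISTA reaches a lower objective than ISTA at equal iteration count", {
  bank <- tiny_bank()
  set.seed(15)
  wins <- 0L
  for (trial in 1:10) {
    lf <- light_field(matrix(runif(625, 0, 2), 25, 25))
    lam <- 0.02 * max(abs(back_project(lf, bank)$data))
    o_ista <- attr(ista_reconstruct(lf, bank, n_iter = 60, lambda = lam,
                                    method = "ista"), "objectives")
    o_fista <- attr(ista_reconstruct(lf, bank, n_iter = 60, lambda = lam,
                                     method = "fista"), "objectives")
    if (tail(o_fista, 1) <= tail(o_ista, 1)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("sparse reconstruction recovers the support of a two-source phantom", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  v0 <- array(0, vd); v0[4, 4, 2] <- 1; v0[6, 6, 4] <- 1
  lf <- forward_project(v0, bank)
  lam <- 0.05 * max(abs(back_project(lf, bank)$data))
  rec <- ista_reconstruct(lf, bank, n_iter = 400, lambda = lam,
                          method = "fista")
  top2 <- order(rec$data, decreasing = TRUE)[1:2]
  expect_setequal(top2, which(v0 > 0))
})

test_that("sparse reconstruction leaves less background energy than 8-iteration RL", {
  bank <- mid_bank()
  vd <- volume_dim(bank$config)
  mask <- array(FALSE, vd)
  mask[3:5, 3:5, 2:3] <- TRUE; mask[6:8, 6:8, 3:4] <- TRUE
  set.seed(16)
  v0 <- array(0, vd); v0[mask] <- runif(sum(mask), 0.5, 1)
  lf <- forward_project(v0, bank)
  rl <- richardson_lucy(lf, bank, n_iter = 8)
  lam <- 0.02 * max(abs(back_project(lf, bank)$data))
  sp <- ista_reconstruct(lf, bank, n_iter = 300, lambda = lam,
                         method = "fista")
  bg <- function(rec) sum(rec$data[!mask]) / max(sum(rec$data), 1e-12)
  expect_lt(bg(sp), bg(rl))
})

test_that("batched video reconstruction equals per-frame reconstruction", {
  bank <- tiny_bank()
  set.seed(17)
  fr <- array(runif(25 * 25 * 3, 0, 2), c(25, 25, 3))
  vid <- lf_video(fr, dark_level = 0)
  V <- reconstruct_video(vid, bank, method = "rl", n_iter = 4)
  for (t in 1:3) {
    ref <- richardson_lucy(light_field(fr[, , t]), bank, n_iter = 4)
    expect_equal(V[, t], as.vector(ref$data), tolerance = 1e-12)
  }
})
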