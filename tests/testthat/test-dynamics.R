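# Forward AR(1) generator for oracle traces.
ar1_trace <- function(n, spikes, gamma) {
  c_t <- numeric(n)
  s <- numeric(n); s[spikes$frame] <- spikes$amp
  for (t in seq_len(n)) c_t[t] <- if (t == 1) s[1] else gamma * c_t[t - 1] + s[t]
  c_t
}

test_that("OASIS inverts noiseless AR(1) traces exactly at lambda 0", {
  gamma <- 0.92
  sp <- data.frame(frame = c(10, 45, 80), amp = c(1, 0.6, 1.4))
  y <- ar1_trace(120, sp, gamma)
  d <- oasis_ar1(y, gamma, lambda = 0)
  expect_equal(d$denoised, y, tolerance = 1e-9)
  expect_equal(which(d$spikes > 1e-9), sp$frame)
  expect_equal(d$spikes[sp$frame], sp$amp, tolerance = 1e-9)
  # AR(1) recursion holds identically
  expect_equal(d$denoised,
               ar1_trace(120, data.frame(frame = which(d$spikes > 0),
                                         amp = d$spikes[d$spikes > 0]), gamma),
               tolerance = 1e-12)
  # flat zero trace -> zero spikes
  expect_equal(max(oasis_ar1(numeric(50), 0.9)$spikes), 0)
  expect_error(oasis_ar1(y, 1.2), "gamma")
  expect_error(oasis_ar1(y, 0.9, lambda = -1), "lambda")
})

test_that("OASIS solution matches the glmnet nonnegative-lasso oracle", {
  skip_if_not_installed("glmnet")
  set.seed(71)
  gamma <- 0.9; n <- 30
  y <- ar1_trace(n, data.frame(frame = c(5, 14, 22), amp = c(1, 0.8, 1.2)),
                 gamma) + rnorm(n, 0, 0.15)
  lambda <- 0.4
  d <- oasis_ar1(y, gamma, lambda = lambda)
  # oracle: c = Ginv s with Ginv lower-triangular gamma powers; solve the
  # nonnegative l1 problem in s with glmnet and map back to c
  Ginv <- outer(seq_len(n), seq_len(n),
                function(i, j) ifelse(i >= j, gamma^(i - j), 0))
  fit <- glmnet::glmnet(Ginv, y, lambda = lambda / n, lower.limits = 0,
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  s_or <- as.numeric(fit$beta)
  c_or <- as.numeric(Ginv %*% s_or)
  expect_equal(d$denoised, c_or, tolerance = 1e-5)
  expect_equal(d$spikes, s_or, tolerance = 1e-5)
})

test_that("increasing lambda weakly decreases the number of active spike bins", {
  set.seed(72)
  gamma <- 0.9
  y <- ar1_trace(200, data.frame(frame = sort(sample(5:195, 12)),
                                 amp = runif(12, 0.5, 1.5)), gamma) +
    rnorm(200, 0, 0.2)
  nnz <- vapply(c(0, 0.1, 0.3, 1, 3),
                function(l) sum(oasis_ar1(y, gamma, l)$spikes > 1e-8),
                numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("putative spike detection finds isolated events at their onset", {
  s <- numeric(100); s[c(20, 60)] <- c(1, 0.8)
  expect_equal(detect_putative_spikes(s), c(20, 60))
  expect_identical(detect_putative_spikes(numeric(50)), integer(0))
  # amplitude threshold suppresses small events
  s2 <- numeric(100); s2[20] <- 1; s2[60] <- 0.05
  expect_equal(detect_putative_spikes(s2, min_amplitude_frac = 0.1), 20)
  expect_error(detect_putative_spikes(c(-1, 0, 1)), "nonnegative")
  # onset refinement maps a spread-out rise back to its first frame
  s3 <- numeric(100); s3[30] <- 0.3; s3[31] <- 0.7; s3[32] <- 0.2
  expect_equal(detect_putative_spikes(s3), 30)
  expect_equal(detect_putative_spikes(s3, refine_onset = FALSE), 31)
})

test_that("spike recall at 100 Hz beats recall after 10x averaging on fast trains", {
  set.seed(73)
  gamma <- exp(-1 / (100 * 0.15))
  rec <- matrix(NA_real_, 8, 2)
  for (k in 1:8) {
    sp <- sort(runif(rpois(1, 50), 0.1, 4.9))
    y <- spikes_to_calcium(sp, duration_s = 5) + rnorm(500, 0, 0.08)
    d1 <- oasis_ar1(y - quantile(y, 0.1), gamma, lambda = 0.1 * mad(diff(y)))
    rec[k, 1] <- spike_recall(detect_putative_spikes(d1$spikes, 0.05), sp, 100)
    yd <- downsample_average(y, 10)
    d2 <- oasis_ar1(yd - quantile(yd, 0.1), gamma^10,
                    lambda = 0.1 * mad(diff(yd)))
    rec[k, 2] <- spike_recall(detect_putative_spikes(d2$spikes, 0.05), sp, 10)
  }
  expect_gte(mean(rec[, 1]), 0.9)
  expect_lt(mean(rec[, 2]), mean(rec[, 1]))
})

test_that("clustering recovers two orthogonal groups of six traces", {
  set.seed(74)
  base1 <- sin(seq(0, 20, length.out = 400))
  base2 <- sign(cos(seq(0, 13, length.out = 400)))
  S <- rbind(
    t(replicate(6, base1 + rnorm(400, 0, 0.1))),
    t(replicate(6, base2 + rnorm(400, 0, 0.1))))
  cl <- cluster_traces(S)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$labels[1:6])), 1)
  expect_equal(length(unique(cl$labels[7:12])), 1)
  expect_false(cl$labels[1] == cl$labels[7])
  # permutation invariance up to label names
  perm <- sample(12)
  cl2 <- cluster_traces(S[perm, ])
  agree <- table(cl$labels[perm], cl2$labels)
  expect_equal(sum(apply(agree, 1, max)), 12)
  # occupancy rule
  expect_equal(cluster_traces(S[1:6, ])$n_clusters, 1)
  expect_equal(cluster_traces(matrix(rnorm(2 * 50), 1))$n_clusters, 1)
})

test_that("within/between cluster distances behave under intermingled vs segregated geometry", {
  set.seed(75)
  # spatially random assignment: no distance difference in most seeds
  p_high <- replicate(20, {
    cent <- cbind(runif(24, 0, 300), runif(24, 0, 300), runif(24, 0, 100))
    labels <- rep(1:4, each = 6)[sample(24)]
    r <- intra_inter_distance_test(labels, cent)
    min(r$mann_whitney_p, r$t_test_p)
  })
  expect_gte(mean(p_high > 0.05), 0.75)
  # segregated blocks: strongly different
  cent <- rbind(cbind(runif(8, 0, 40), runif(8, 0, 40), runif(8, 0, 30)),
                cbind(runif(8, 260, 300), runif(8, 260, 300), runif(8, 0, 30)))
  r <- intra_inter_distance_test(rep(1:2, each = 8), cent)
  expect_lt(r$mann_whitney_p, 0.01)
  expect_lt(r$t_test_p, 0.01)
  expect_lt(r$medians["intra"], r$medians["inter"])
  # two clusters of one pair each, hand enumeration
  cent4 <- rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0), c(10, 4, 0))
  r4 <- intra_inter_distance_test(c(1, 1, 2, 2), cent4)
  expect_setequal(round(r4$intra_distances, 6), c(3, 4))
  expect_equal(length(r4$inter_distances), 4)
  expect_error(intra_inter_distance_test(rep(1, 4), cent4), "two clusters")
})
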