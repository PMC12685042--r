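#' Build a per-depth light-field PSF bank
#'
#' Constructs the filter-bank representation of the LFM forward model: for
#' every reconstruction depth and every sub-lenslet lateral phase, a
#' nonnegative, unit-sum sensor kernel giving the response to a unit point
#' source. The kernels are periodic in the lenslet pitch: translating a source
#' by one lenslet translates its footprint by `pixels_per_lenslet` pixels.
#'
#' The default `"geometric"` mode ray-traces the MLA acceptance cone: each
#' within-lenslet pixel samples one ray angle `a` inside the cone of
#' half-angle `atan(M / (2 f#))` (object side), and a source at depth `z` and
#' lateral position `u` sends the ray with angle `a` to lenslet coordinate
#' `u + z a` (the epipolar-line geometry of a light field). Energy is split
#' bilinearly between the two neighboring lenslets and finally blurred with a
#' small anti-alias Gaussian (sigma 0.5 px). At `z = 0` the whole footprint
#' collapses into the source's lenslet; with growing `|z|` it spreads over a
#' defocus disk of lenslets. `"fresnel"` mode additionally convolves every
#' kernel with a diffraction-limited Gaussian spot (Gaussian approximation of
#' the MLA-aperture Airy pattern) of width set by the emission wavelength and
#' lenslet f-number.
#'
#' @param config An [lfm_config()].
#' @param mode `"geometric"` (default) or `"fresnel"`.
#' @return A `psf_bank`: per-depth, per-phase kernels plus a cache for the
#'   assembled sparse forward operator.
#' @export
build_psf_bank <- function(config, mode = c("geometric", "fresnel")) {
  mode <- match.arg(mode)
  validate_lfm_config(config)
  s <- config$lateral_supersampling
  ppl <- config$pixels_per_lenslet
  h <- (ppl - 1L) / 2
  pitch_obj <- lenslet_pitch_object_um(config)
  tan_alpha <- config$magnification / (2 * config$mla_f_number)
  zg <- z_depths_um(config)

  # Angular samples: within-lenslet pixels inside the acceptance circle.
  ang <- expand.grid(ai = -h:h, aj = -h:h)
  ang <- ang[ang$ai^2 + ang$aj^2 <= h^2 + 1e-9, , drop = FALSE]
  a_y <- ang$ai / h * tan_alpha
  a_x <- ang$aj / h * tan_alpha
  w0 <- 1 / nrow(ang)

  blur_sigma <- 0.5
  if (mode == "fresnel") {
    diff_sigma <- 0.45 * config$emission_wavelength_um * config$mla_f_number /
      config$camera_pixel_um
    blur_sigma <- sqrt(blur_sigma^2 + diff_sigma^2)
  }

  kernels <- vector("list", config$n_z)
  for (k in seq_len(config$n_z)) {
    z <- zg[k]
    Lh <- as.integer(ceiling((abs(z) * tan_alpha + pitch_obj) / pitch_obj)) + 1L
    npat <- (2L * Lh + 1L) * ppl
    phase_list <- vector("list", s * s)
    for (py in seq_len(s) - 1L) {
      for (px in seq_len(s) - 1L) {
        u_y <- (py - (s - 1) / 2) / s * pitch_obj
        u_x <- (px - (s - 1) / 2) / s * pitch_obj
        # landing position in lenslet units, relative to the source lenslet
        sy <- (u_y + z * a_y) / pitch_obj
        sx <- (u_x + z * a_x) / pitch_obj
        fy <- floor(sy); fx <- floor(sx)
        ry <- sy - fy;   rx <- sx - fx
        pat <- matrix(0, npat, npat)
        # bilinear split across the 4 neighboring lenslets at this pixel angle
        for (q in 1:4) {
          dly <- fy + (q == 2 | q == 4)
          dlx <- fx + (q == 3 | q == 4)
          wq <- switch(q,
                       (1 - ry) * (1 - rx),
                       ry * (1 - rx),
                       (1 - ry) * rx,
                       ry * rx)
          rr <- (dly + Lh) * ppl + (ang$ai + h) + 1
          cc <- (dlx + Lh) * ppl + (ang$aj + h) + 1
          keep <- rr >= 1 & rr <= npat & cc >= 1 & cc <= npat & wq > 0
          if (any(keep)) {
            idx <- cbind(rr[keep], cc[keep])
            vals <- w0 * wq[keep]
            for (t in seq_len(nrow(idx)))
              pat[idx[t, 1], idx[t, 2]] <- pat[idx[t, 1], idx[t, 2]] + vals[t]
          }
        }
        pat <- gauss_blur_2d(pat, blur_sigma)
        pat[pat < max(pat) * 1e-10] <- 0
        pat <- pat / sum(pat)
        phase_list[[py * s + px + 1L]] <-
          list(m = pat, o = -Lh * ppl)  # sensor index = (lenslet-1)*ppl + o + patch index
      }
    }
    kernels[[k]] <- phase_list
  }

  structure(list(config = config, mode = mode, z_um = zg, kernels = kernels,
                 cache = new.env(parent = emptyenv())),
            class = "psf_bank")
}

#' @export
print.psf_bank <- function(x, ...) {
  cat(sprintf("<psf_bank> mode %s, %d depths x %d phases, period %d px\n",
              x$mode, length(x$kernels), length(x$kernels[[1]]),
              x$config$pixels_per_lenslet))
  invisible(x)
}

#' Materialize the linear forward operator of a PSF bank
#'
#' Assembles (and caches inside the bank) the sparse matrix `A` mapping a
#' vectorized volume to a vectorized light field. `forward_project()` computes
#' `A v` and `back_project()` the exact adjoint `A' l`.
#'
#' @param bank A [build_psf_bank()] result.
#' @return A `Matrix::sparseMatrix` with `prod(sensor_dim)` rows and
#'   `prod(volume_dim)` columns.
#' @export
forward_operator <- function(bank) {
  if (!is.null(bank$cache$A)) return(bank$cache$A)
  cfg <- bank$config
  s <- cfg$lateral_supersampling
  ppl <- cfg$pixels_per_lenslet
  nly <- cfg$n_lenslets_y; nlx <- cfg$n_lenslets_x
  H <- nly * ppl; W <- nlx * ppl
  ny <- nly * s; nx <- nlx * s
  lg_ly <- rep(seq_len(nly), times = nlx)
  lg_lx <- rep(seq_len(nlx), each = nly)
  nL <- length(lg_ly)
  acc_i <- acc_j <- acc_x <- vector("list", cfg$n_z * s * s)
  n_acc <- 0L
  for (k in seq_len(cfg$n_z)) {
    for (py in seq_len(s) - 1L) {
      for (px in seq_len(s) - 1L) {
        ker <- bank$kernels[[k]][[py * s + px + 1L]]
        nzk <- which(ker$m != 0)
        if (!length(nzk)) next
        kv <- ker$m[nzk]
        npat <- nrow(ker$m)
        kr <- ((nzk - 1L) %% npat) + 1L + ker$o
        kc <- ((nzk - 1L) %/% npat) + 1L + ker$o
        m <- length(kv)
        srow <- rep((lg_ly - 1L) * ppl, times = m) + rep(kr, each = nL)
        scol <- rep((lg_lx - 1L) * ppl, times = m) + rep(kc, each = nL)
        vy <- (lg_ly - 1L) * s + py + 1L
        vx <- (lg_lx - 1L) * s + px + 1L
        vlin <- vy + (vx - 1L) * ny + (k - 1L) * ny * nx
        ok <- srow >= 1L & srow <= H & scol >= 1L & scol <= W
        n_acc <- n_acc + 1L
        acc_i[[n_acc]] <- (srow + (scol - 1L) * H)[ok]
        acc_j[[n_acc]] <- rep(vlin, times = m)[ok]
        acc_x[[n_acc]] <- rep(kv, each = nL)[ok]
      }
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(acc_i), j = unlist(acc_j),
                            x = unlist(acc_x),
                            dims = c(H * W, ny * nx * cfg$n_z))
  bank$cache$A <- A
  A
}

# Column sums of A (per-voxel sensitivity), cached; used by Richardson-Lucy.
operator_sensitivity <- function(bank) {
  if (is.null(bank$cache$sens)) {
    bank$cache$sens <- Matrix::colSums(forward_operator(bank))
  }
  bank$cache$sens
}

# Largest eigenvalue of A'A by power iteration (cached), for ISTA step sizes.
operator_lipschitz <- function(bank, n_iter = 30L) {
  if (!is.null(bank$cache$L)) return(bank$cache$L)
  A <- forward_operator(bank)
  n <- ncol(A)
  v <- rep(1, n) + sin(seq_len(n))  # deterministic non-degenerate start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(n_iter)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) break
    v <- w / lam
  }
  bank$cache$L <- lam * 1.05  # small safety margin over the estimate
  bank$cache$L
}

check_volume_shape <- function(v, bank) {
  d <- dim(as_volume_array(v))
  if (length(d) != 3L || !all(d == volume_dim(bank$config)))
    stop("volume shape does not match the PSF bank configuration", call. = FALSE)
}

check_lf_shape <- function(l, bank) {
  d <- dim(as_lf_matrix(l))
  if (length(d) != 2L || !all(d == sensor_dim(bank$config)))
    stop("light-field shape does not match the PSF bank configuration", call. = FALSE)
}

#' Forward and adjoint light-field projection
#'
#' `forward_project()` applies the linear LFM forward model to a volume,
#' producing the light field a camera would record (up to noise);
#' `back_project()` applies the exact transpose, mapping a light field back
#' into the volume grid (the "backprojection volume").
#'
#' @param v An [lfm_volume()] or bare 3D array on the bank's grid.
#' @param l A [light_field()] or bare matrix on the bank's sensor grid.
#' @param bank A [build_psf_bank()] result.
#' @return `forward_project()`: a `light_field`; `back_project()`: an
#'   `lfm_volume`.
#' @export
forward_project <- function(v, bank) {
  check_volume_shape(v, bank)
  A <- forward_operator(bank)
  lf <- as.numeric(A %*% as.vector(as_volume_array(v)))
  light_field(matrix(lf, sensor_dim(bank$config)[1], sensor_dim(bank$config)[2]))
}

#' @rdname forward_project
#' @export
back_project <- function(l, bank) {
  check_lf_shape(l, bank)
  A <- forward_operator(bank)
  v <- as.numeric(Matrix::crossprod(A, as.vector(as_lf_matrix(l))))
  lfm_volume(array(v, volume_dim(bank$config)), bank$config)
}
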