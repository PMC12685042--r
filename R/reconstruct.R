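# Model-based volume estimation from light fields. Both solvers operate on
# the sparse forward operator and accept a matrix of vectorized light fields,
# so a whole video can be reconstructed in one batched call.

rl_core <- function(Lmat, bank, n_iter = 8L, eps = 1e-12) {
  A <- forward_operator(bank)
  sens <- operator_sensitivity(bank)
  sens[sens == 0] <- 1  # voxels invisible to the sensor stay zero
  V <- as.matrix(Matrix::crossprod(A, Lmat))  # backprojection initialization
  for (it in seq_len(n_iter)) {
    pred <- as.matrix(A %*% V)
    ratio <- Lmat / pmax(pred, eps)
    V <- V * as.matrix(Matrix::crossprod(A, ratio)) / sens
  }
  V
}

ista_core <- function(Lmat, bank, n_iter = 100L, lambda = 0,
                      step = NULL, accelerate = FALSE, nonneg = TRUE,
                      init = c("zeros", "backprojection"),
                      track_objective = TRUE) {
  init <- match.arg(init)
  A <- forward_operator(bank)
  if (is.null(step)) step <- 1 / operator_lipschitz(bank)
  V <- if (init == "zeros") {
    matrix(0, ncol(A), ncol(Lmat))
  } else {
    as.matrix(Matrix::crossprod(A, Lmat))
  }
  Y <- V
  tk <- 1
  obj <- function(V) {
    R <- as.matrix(A %*% V) - Lmat
    0.5 * sum(R^2) + lambda * sum(abs(V))
  }
  objectives <- if (track_objective) numeric(n_iter) else NULL
  prev_obj <- Inf; rising <- 0L
  for (it in seq_len(n_iter)) {
    G <- as.matrix(Matrix::crossprod(A, as.matrix(A %*% Y) - Lmat))
    Vn <- Y - step * G
    # proximal step: (nonnegative) soft threshold
    Vn <- Vn - sign(Vn) * pmin(abs(Vn), lambda * step)
    if (nonneg) Vn[Vn < 0] <- 0
    if (accelerate) {
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Y <- Vn + ((tk - 1) / tn) * (Vn - V)
      tk <- tn
    } else {
      Y <- Vn
    }
    V <- Vn
    if (track_objective) {
      objectives[it] <- obj(V)
      if (!accelerate) {
        if (!is.finite(objectives[it]) ||
            objectives[it] > prev_obj * (1 + 1e-10)) rising <- rising + 1L else rising <- 0L
        if (rising >= 2L || !is.finite(objectives[it]))
          stop("ISTA objective increased on two consecutive iterations; ",
               "decrease the step size", call. = FALSE)
        prev_obj <- objectives[it]
      }
    }
  }
  list(V = V, objectives = objectives, step = step)
}

#' Richardson-Lucy volume reconstruction
#'
#' Multiplicative RL deconvolution of a light field into a 3D volume:
#' `v <- v * A'(l / A v) / A' 1`, initialized with the backprojection volume
#' `A' l`. Eight iterations are the benchmark setting for calcium activity
#' volumes. Iterates are nonnegative by construction; the Poisson ratio is
#' guarded by `eps` against division by zero.
#'
#' @param l A [light_field()] or matrix of sensor counts. Must be nonnegative:
#'   subtract the camera dark level first.
#' @param bank A [build_psf_bank()].
#' @param n_iter Number of RL iterations (default 8).
#' @param eps Guard added to the model prediction before division.
#' @return An [lfm_volume()].
#' @export
richardson_lucy <- function(l, bank, n_iter = 8L, eps = 1e-12) {
  check_lf_shape(l, bank)
  lm <- as_lf_matrix(l)
  if (min(lm) < 0)
    stop("light field has negative values; subtract the dark level before ",
         "Richardson-Lucy", call. = FALSE)
  V <- rl_core(matrix(as.vector(lm), ncol = 1L), bank, n_iter = n_iter,
               eps = eps)
  lfm_volume(array(V[, 1L], volume_dim(bank$config)), bank$config)
}

#' Sparsity-promoting reconstruction by ISTA / FISTA
#'
#' Solves `min_v 0.5 ||A v - l||^2 + lambda ||v||_1, v >= 0` by proximal
#' gradient descent (ISTA) or its accelerated variant (FISTA). This is the
#' classical form of the optimization that physics-based unrolled networks
#' trained for scattering mitigation implement layer by layer; the compact
#' somata of a calcium activity volume make the reconstruction naturally
#' sparse.
#'
#' @param l A [light_field()] or matrix (dark level already subtracted).
#' @param bank A [build_psf_bank()].
#' @param n_iter Iteration count.
#' @param lambda Nonnegative l1 weight (absolute scale).
#' @param step Gradient step size; `NULL` (default) uses `1/L` with `L` the
#'   largest eigenvalue of `A'A` estimated by power iteration.
#' @param method `"ista"` (monotone) or `"fista"` (accelerated).
#' @param nonneg Constrain the volume to be nonnegative (default `TRUE`).
#' @param init `"zeros"` or `"backprojection"`.
#' @return An [lfm_volume()] with attribute `objectives` (per-iteration value
#'   of the penalized least-squares objective).
#' @export
ista_reconstruct <- function(l, bank, n_iter = 100L, lambda = 0, step = NULL,
                             method = c("ista", "fista"), nonneg = TRUE,
                             init = c("zeros", "backprojection")) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  check_lf_shape(l, bank)
  res <- ista_core(matrix(as.vector(as_lf_matrix(l)), ncol = 1L), bank,
                   n_iter = n_iter, lambda = lambda, step = step,
                   accelerate = method == "fista", nonneg = nonneg,
                   init = init)
  out <- lfm_volume(array(res$V[, 1L], volume_dim(bank$config)), bank$config)
  attr(out, "objectives") <- res$objectives
  attr(out, "step") <- res$step
  out
}

#' Reconstruct every frame of a light-field video
#'
#' Batched per-frame reconstruction used by the ROI trace-extraction method.
#' Frames are dark-level subtracted, clipped at zero, and reconstructed with
#' the requested solver.
#'
#' @param video An [lf_video()].
#' @param bank A [build_psf_bank()].
#' @param method `"rl"`, `"ista"`, or `"fista"`.
#' @param n_iter Iterations per frame.
#' @param lambda l1 weight for the sparse solvers.
#' @param ... Passed on to the solver core.
#' @return A `n_voxels x n_frames` matrix of vectorized volumes, with
#'   attribute `dim3` giving the volume grid dimensions.
#' @export
reconstruct_video <- function(video, bank, method = c("rl", "ista", "fista"),
                              n_iter = if (method == "rl") 8L else 50L,
                              lambda = 0, ...) {
  method <- match.arg(method)
  Lmat <- pmax(video_matrix(video) - video$dark_level, 0)
  V <- if (method == "rl") {
    rl_core(Lmat, bank, n_iter = n_iter, ...)
  } else {
    ista_core(Lmat, bank, n_iter = n_iter, lambda = lambda,
              accelerate = method == "fista", track_objective = FALSE, ...)$V
  }
  attr(V, "dim3") <- volume_dim(bank$config)
  V
}
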