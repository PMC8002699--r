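#' Particle filter configuration
#'
#' The seven tunables recorded per run are `(n_trans, n_rot, vf, w_exp,
#' w_gaus, w_uni, k)`; `dt`, the occlusion rate `lam` and the sensor-noise
#' parameters `df`/`bn` complete the observation model. Time is measured in
#' frames (`dt = 1`), so the noise magnitudes are per-frame quantities.
#'
#' @param n_trans Translational velocity noise std (meters/frame).
#' @param n_rot Rotational velocity noise std (per quaternion component,
#'   dimensionless per frame).
#' @param vf Velocity decay factor in `(0, 1]`.
#' @param w_exp,w_gaus,w_uni Mixture weights of the exponential (occlusion),
#'   Gaussian (sensor noise) and uniform (random return) likelihood terms.
#'   They are not renormalized: the likelihood is an unnormalized score,
#'   which is harmless for the argmax and for thresholding.
#' @param k Particle count (>= 1).
#' @param dt Integration time step (frames; default 1).
#' @param lam Occlusion exponential rate (1/meter).
#' @param df,bn Assumed sensor noise: Gaussian variance at expected depth
#'   `x` is `df * x^2 + bn`.
#' @return Object of class `"filter_config"`.
#' @export
filter_config <- function(n_trans = 0.005, n_rot = 0.02, vf = 0.9,
                          w_exp = 0.3, w_gaus = 0.6, w_uni = 0.1,
                          k = 200, dt = 1, lam = 1.0,
                          df = 1e-5, bn = 4e-6) {
  stopifnot(k >= 1, vf > 0, vf <= 1, lam > 0,
            w_exp >= 0, w_gaus >= 0, w_uni >= 0,
            w_exp + w_gaus + w_uni > 0)
  structure(list(n_trans = n_trans, n_rot = n_rot, vf = vf,
                 w_exp = w_exp, w_gaus = w_gaus, w_uni = w_uni,
                 k = as.integer(k), dt = dt, lam = lam, df = df, bn = bn),
            class = "filter_config")
}

#' The seven recorded configuration values of a filter config
#'
#' @param cfg [filter_config()].
#' @return Named numeric vector `(n_trans, n_rot, vf, w_exp, w_gaus, w_uni,
#'   k)` — the per-run configuration part of the feature vector.
#' @export
config_vector <- function(cfg) {
  c(n_trans = cfg$n_trans, n_rot = cfg$n_rot, vf = cfg$vf,
    w_exp = cfg$w_exp, w_gaus = cfg$w_gaus, w_uni = cfg$w_uni,
    k = as.numeric(cfg$k))
}

#' Predict a set of particles from a reference pose
#'
#' Each particle draws new velocities `v' = vf * v + eps * dt` (Gaussian
#' `eps`, std `n_trans` per translational axis and `n_rot` per
#' rotational-quaternion component) and then integrates position and
#' orientation with the *new* velocities (backward Euler):
#' `p' = p + v'_trans * dt`, `q' = normalize(q + 0.5 (q x v'_rot) dt)`.
#' Uses the R RNG.
#'
#' @param ref Reference [pose()].
#' @param cfg [filter_config()].
#' @return Object of class `"particle_set"`: list of matrices `p` (k x 3),
#'   `q` (k x 4, unit rows), `v_trans` (k x 3), `v_rot` (k x 4).
#' @export
predict_particles <- function(ref, cfg) {
  stopifnot(inherits(ref, "pose"), inherits(cfg, "filter_config"))
  k <- cfg$k
  dt <- cfg$dt
  vt <- matrix(rep(cfg$vf * ref$v_trans, each = k), k, 3) +
    matrix(stats::rnorm(3 * k, 0, cfg$n_trans), k, 3) * dt
  vr <- matrix(rep(cfg$vf * ref$v_rot, each = k), k, 4) +
    matrix(stats::rnorm(4 * k, 0, cfg$n_rot), k, 4) * dt
  p <- matrix(rep(ref$p, each = k), k, 3) + vt * dt
  # q + 0.5 * (q x v_rot) * dt, rowwise Hamilton product with fixed q
  q0 <- ref$q
  qd <- cbind(q0[1] * vr[, 1] - q0[2] * vr[, 2] - q0[3] * vr[, 3] - q0[4] * vr[, 4],
              q0[1] * vr[, 2] + q0[2] * vr[, 1] + q0[3] * vr[, 4] - q0[4] * vr[, 3],
              q0[1] * vr[, 3] - q0[2] * vr[, 4] + q0[3] * vr[, 1] + q0[4] * vr[, 2],
              q0[1] * vr[, 4] + q0[2] * vr[, 3] - q0[3] * vr[, 2] + q0[4] * vr[, 1])
  q <- matrix(rep(q0, each = k), k, 4) + 0.5 * qd * dt
  nrm <- sqrt(rowSums(q^2))
  nrm[nrm < 1e-12] <- 1
  q <- q / nrm
  structure(list(p = p, q = q, v_trans = vt, v_rot = vr),
            class = "particle_set")
}

#' Extract one particle of a particle set as a pose
#'
#' @param particles A `"particle_set"`.
#' @param i Particle index.
#' @return A [pose()].
#' @export
particle_pose <- function(particles, i) {
  pose(particles$p[i, ], particles$q[i, ],
       particles$v_trans[i, ], particles$v_rot[i, ])
}

#' Per-pixel observation log-likelihood
#'
#' Mixture log-likelihood of an observed depth `x_o` given an expected depth
#' `x_e` (both possibly invalid, encoded `NA`), in nats:
#' \itemize{
#'   \item `x_e` invalid: 0 — an expected-background pixel fits any
#'     observation;
#'   \item `x_o` invalid: `ln(w_uni / (d_max - d_min))` — a dropped return is
#'     explained by the uniform term alone;
#'   \item `x_e >= x_o`: `ln(uniform + Gaussian + truncated exponential)` —
#'     an observation at or nearer than the expectation may be an occlusion,
#'     modeled by `lam * exp(-lam * x_o) / (1 - exp(-lam * x_e))`;
#'   \item `x_e < x_o`: `ln(uniform + Gaussian)`.
#' }
#' The Gaussian has mean `x_e` and variance `df * x_e^2 + bn`.
#'
#' @param x_o,x_e Observed / expected depths (vectors, `NA` = invalid).
#' @param cfg [filter_config()] (mixture weights, `lam`, `df`, `bn`).
#' @param intr [camera_intrinsics()] (`d_min`, `d_max`).
#' @return Log-likelihood in nats, vectorized over pixels.
#' @export
#' @examples
#' cfg <- filter_config(w_uni = 0.1)
#' intr <- camera_intrinsics(d_min = 0.3, d_max = 3.0)
#' pixel_log_likelihood(NA, NA, cfg, intr)    # expected invalid: 0
#' pixel_log_likelihood(NA, 0.6, cfg, intr)   # observed invalid: log(0.1/2.7)
pixel_log_likelihood <- function(x_o, x_e, cfg, intr) {
  stopifnot(inherits(cfg, "filter_config"), inherits(intr, "camera_intrinsics"))
  n <- max(length(x_o), length(x_e))
  .pixel_ll_cpp(rep_len(as.numeric(x_o), n), rep_len(as.numeric(x_e), n),
                cfg$w_uni, cfg$w_gaus, cfg$w_exp, cfg$lam, cfg$df, cfg$bn,
                intr$d_min, intr$d_max)
}

#' Image log-likelihood weight of a particle
#'
#' The particle weight is the sum of [pixel_log_likelihood()] over all pixel
#' pairs of the observed and expected depth images.
#'
#' @param observed,expected Depth matrices of identical shape.
#' @param cfg [filter_config()].
#' @param intr [camera_intrinsics()].
#' @return Scalar log-weight in nats.
#' @export
particle_weight <- function(observed, expected, cfg, intr) {
  if (!all(dim(observed) == dim(expected))) {
    stop("observed and expected images must have the same shape", call. = FALSE)
  }
  .image_weight_cpp(observed, expected,
                    cfg$w_uni, cfg$w_gaus, cfg$w_exp, cfg$lam, cfg$df, cfg$bn,
                    intr$d_min, intr$d_max)
}

#' Log-domain effective sample size
#'
#' For log-weights `w`, normalizes via log-sum-exp (`w~ = w - LSE(w)`) and
#' returns `-ln sum(exp(2 w~)) = 2 LSE(w) - LSE(2 w)` — the natural log of
#' the standard effective sample size `1 / sum(p_i^2)`. Lies in
#' `[0, ln K]`; equals `ln K` iff all weights are equal, 0 when one particle
#' carries all the weight.
#'
#' @param log_weights Numeric vector of K finite log-weights (a `-Inf`
#'   entry is allowed and means zero weight).
#' @return ESS in nats.
#' @export
effective_sample_size <- function(log_weights) {
  if (!length(log_weights)) stop("empty weight vector", call. = FALSE)
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  ess <- 2 * lse(log_weights) - lse(2 * log_weights)
  # clamp tiny negative rounding
  min(max(ess, 0), log(length(log_weights)))
}

#' One particle-filter update step
#'
#' Predicts `k` particles around the reference pose, scores each against the
#' observation with the image log-likelihood, and returns the argmax-weight
#' particle as the new tracked pose together with the per-frame diagnostics
#' (max log-likelihood, log-domain ESS, mean and variance of the raw
#' log-weights). Ties at the maximum resolve to the lowest particle index.
#'
#' @param ref Current tracked [pose()].
#' @param observation Observed depth matrix.
#' @param cfg [filter_config()].
#' @param intr [camera_intrinsics()].
#' @param target_shape [target_sphere()] or [target_box()].
#' @return List with `pose` (new tracked pose) and `output` (named numeric
#'   `(ll_max, ess, w_mean, w_var)`).
#' @export
filter_step <- function(ref, observation, cfg, intr, target_shape) {
  particles <- predict_particles(ref, cfg)
  w <- .weight_particles_cpp(observation, particles$p, particles$q,
                             target_shape$type, target_shape$params,
                             unclass(intr),
                             cfg$w_uni, cfg$w_gaus, cfg$w_exp,
                             cfg$lam, cfg$df, cfg$bn)
  best <- which.max(w)
  out <- c(ll_max = w[best],
           ess = effective_sample_size(w),
           w_mean = mean(w),
           w_var = if (length(w) > 1) stats::var(w) else 0)
  list(pose = particle_pose(particles, best), output = out)
}

#' Track a full sequence and record the per-frame diagnostics
#'
#' Runs one [filter_step()] per frame starting from `init` (defaulting to
#' the ground-truth pose of frame 1, i.e. manual initialization at the
#' correct position) and records, per frame, the filter diagnostics and the
#' error labels against ground truth: `delta` = Euclidean position error
#' (meters) and `alpha` = [angular_difference()] (radians).
#'
#' @param seq A `"depth_sequence"` from [simulate_sequence()].
#' @param cfg [filter_config()].
#' @param intr [camera_intrinsics()]; defaults to the sequence's own.
#' @param init Initial [pose()]; default ground truth at frame 1.
#' @param seed Optional integer seed applied before tracking, making the
#'   whole trace reproducible.
#' @return A `"tracking_trace"` data frame with columns `frame, ll_max, ess,
#'   w_mean, w_var, delta, alpha, px, py, pz, qw, qx, qy, qz`.
#' @export
track_sequence <- function(seq, cfg, intr = seq$intr, init = NULL,
                           seed = NULL) {
  stopifnot(inherits(seq, "depth_sequence"), inherits(cfg, "filter_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(seq$frames)
  cols <- c("frame", "ll_max", "ess", "w_mean", "w_var", "delta", "alpha",
            "px", "py", "pz", "qw", "qx", "qy", "qz")
  if (n == 0) {
    tr <- as.data.frame(matrix(numeric(0), 0, length(cols),
                               dimnames = list(NULL, cols)))
    class(tr) <- c("tracking_trace", "data.frame")
    return(tr)
  }
  ref <- if (is.null(init)) seq$poses[[1]] else init
  rows <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  shape <- seq$cfg$target_shape
  for (t in seq_len(n)) {
    st <- filter_step(ref, seq$frames[[t]], cfg, intr, shape)
    ref <- st$pose
    truth <- seq$poses[[t]]
    rows[t, ] <- c(t, st$output,
                   sqrt(sum((ref$p - truth$p)^2)),
                   angular_difference(ref$q, truth$q),
                   ref$p, ref$q)
  }
  tr <- as.data.frame(rows)
  class(tr) <- c("tracking_trace", "data.frame")
  tr
}

#' Write a tracking trace to CSV
#'
#' @param trace A `"tracking_trace"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
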