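# Generative model for phase-coupled alpha oscillators.
#
# Phases are built as a carrier at the center frequency plus wrapped
# Gaussian phase noise that is correlated across sources:
#
#   phi_k(t) = 2 pi f0 t + sigma z_k(t),   z(t) ~ stationary AR(1),
#   cov(z(t)) = R  (unit diagonal).
#
# Because the phase difference of a pair (k, l) is Gaussian with
# variance 2 sigma^2 (1 - R_kl), its circular resultant has the closed
# form  PLV_kl = exp(-sigma^2 (1 - R_kl)),  which is inverted to choose
# R for any achievable target PLV matrix.  The realized PLV is therefore
# known exactly and verifiable with the PLV estimator itself.
# Uncoupled sources (target 0) use R = 0 and land on the model's
# decoherence floor exp(-sigma^2) (~0.018 at the default sigma).

#' Map a target PLV matrix to a latent Gaussian coupling matrix
#'
#' @param target_plv symmetric matrix of target PLVs in `[0, 1]`.
#' @param phase_noise_sd sigma of the wrapped Gaussian phase noise (rad).
#' @return correlation matrix `R` for the latent AR(1) noise.
#' @keywords internal
plv_to_coupling <- function(target_plv, phase_noise_sd = 2) {
  s2 <- phase_noise_sd^2
  p <- as.matrix(target_plv)
  if (!isSymmetric(unname(p), tol = 1e-10)) {
    stop("`target_plv` must be symmetric", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("target PLVs must lie in [0, 1]", call. = FALSE)
  floor_p <- exp(-2 * s2)
  low <- p > 0 & p < floor_p
  if (any(low)) {
    ij <- which(low, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "target PLV %.3g for pair (%d, %d) is below the achievable floor %.3g at phase_noise_sd = %.3g",
      p[ij[1], ij[2]], ij[1], ij[2], floor_p, phase_noise_sd), call. = FALSE)
  }
  R <- matrix(0, nrow(p), ncol(p))
  pos <- p > 0
  R[pos] <- 1 + log(p[pos]) / s2
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    v <- ev$vectors[, which.min(ev$values)]
    worst <- order(abs(v), decreasing = TRUE)[1:2]
    stop(sprintf(
      "target PLV matrix is infeasible (coupling matrix not positive semidefinite); the pair (%d, %d) is the most implicated",
      min(worst), max(worst)), call. = FALSE)
  }
  R
}

# Nearest feasible coupling matrix: alternating projection between the
# PSD cone and the unit-diagonal correlation set.  Used by the cohort
# generator, where per-subject jitter can push an otherwise feasible
# target slightly outside the cone; the projected matrix defines the
# subject's realized ground truth.
nearest_feasible_coupling <- function(R, max_iter = 50L, tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
    if (min(ev$values) >= -tol) break
    R <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(R)) %*% t(ev$vectors)
    d <- sqrt(pmax(diag(R), .Machine$double.eps))
    R <- R / tcrossprod(d)
    diag(R) <- 1
    R[R > 1] <- 1
    R[R < -1] <- -1
  }
  (R + t(R)) / 2
}

# Entry-wise PLV <-> latent-coupling maps (no feasibility checks).
plv_to_coupling_raw <- function(p, phase_noise_sd) {
  s2 <- phase_noise_sd^2
  R <- matrix(0, nrow(p), ncol(p))
  pos <- p > 0
  R[pos] <- 1 + log(p[pos]) / s2
  diag(R) <- 1
  R
}

coupling_to_plv <- function(R, phase_noise_sd) {
  s2 <- phase_noise_sd^2
  p <- exp(-s2 * (1 - R))
  diag(p) <- 1
  p
}

# Phase generation given a valid latent coupling matrix.  Each source
# receives a static random phase offset: pairwise PLV is invariant to
# constant offsets, but the offsets randomize the signs of zero-lag
# amplitude correlations, so coupled sources are not all instantaneously
# correlated (which both mimics lagged physiological coupling and avoids
# the classical correlated-source cancellation of minimum-variance
# beamformers downstream).
simulate_phases_from_coupling <- function(R, n_samples, rate, center_freq,
                                          phase_noise_sd, ar_tau, seed,
                                          static_offsets = TRUE) {
  n_sources <- nrow(R)
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_sources)
  a <- exp(-1 / (rate * ar_tau))
  burn <- ceiling(5 * rate * ar_tau)
  n_tot <- n_samples + burn
  sim <- local_seed(seed, {
    innov <- matrix(stats::rnorm(n_tot * n_sources), n_tot, n_sources) %*% t(A)
    innov <- innov * sqrt(1 - a^2)
    z <- apply(innov, 2, function(col) as.numeric(stats::filter(col, a, method = "recursive")))
    offs <- if (static_offsets) stats::runif(n_sources, -pi, pi) else numeric(n_sources)
    list(z = z, offs = offs)
  })
  z <- sim$z[(burn + 1L):n_tot, , drop = FALSE]
  tt <- (seq_len(n_samples) - 1L) / rate
  carrier <- 2 * pi * center_freq * tt
  phases <- t(z) * phase_noise_sd + sim$offs +
    matrix(carrier, n_sources, n_samples, byrow = TRUE)
  phases <- wrap_phase(phases)
  attr(phases, "rate") <- rate
  attr(phases, "center_freq") <- center_freq
  phases
}

#' Simulate phase time series with a prescribed pairwise PLV structure
#'
#' Generates per-source instantaneous phases advancing on average at
#' `center_freq`, whose pairwise phase-locking values converge to
#' `target_plv` as the number of samples grows.
#'
#' @param n_sources number of sources.
#' @param target_plv `n_sources x n_sources` symmetric matrix of target
#'   PLVs in `[0, 1]`; entries of exactly 0 request independent phase
#'   noise (realized PLV at the decoherence floor `exp(-sigma^2)`).
#' @param n_samples samples to generate.
#' @param rate sampling rate (Hz).
#' @param center_freq oscillation frequency (Hz).
#' @param phase_noise_sd sigma of the phase noise in radians (default 2);
#'   sets the decoherence floor `exp(-sigma^2)`.
#' @param ar_tau correlation time of the phase noise in seconds; controls
#'   the spectral linewidth (~`sigma^2 / (2 pi ar_tau)` Hz).
#' @param seed integer seed.
#' @return matrix `n_sources x n_samples` of phases in `(-pi, pi]`, with
#'   attributes `rate` and `center_freq`.
#' @export
simulate_coupled_phases <- function(n_sources, target_plv, n_samples,
                                    rate = 1000, center_freq = 10,
                                    phase_noise_sd = 2, ar_tau = 0.2,
                                    seed = NULL) {
  target_plv <- as.matrix(target_plv)
  if (nrow(target_plv) != n_sources || ncol(target_plv) != n_sources) {
    stop("`target_plv` must be n_sources x n_sources", call. = FALSE)
  }
  R <- plv_to_coupling(target_plv, phase_noise_sd)
  simulate_phases_from_coupling(R, n_samples, rate, center_freq,
                                phase_noise_sd, ar_tau, seed)
}

#' Turn phase series into oscillatory source signals
#'
#' Each source signal is `amplitude * cos(phase)` plus white Gaussian
#' noise. With zero noise the output is a deterministic function of the
#' phases.
#'
#' @param phases matrix `n_sources x n_samples` of phases (radians).
#' @param amplitude peak oscillation amplitude (scalar or per source).
#' @param noise_sd standard deviation of additive white noise (>= 0).
#' @param seed integer seed for the noise.
#' @return matrix `n_sources x n_samples` of source signals.
#' @export
phases_to_source_signals <- function(phases, amplitude = 1, noise_sd = 0,
                                     seed = NULL) {
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (any(amplitude < 0)) stop("`amplitude` must be non-negative", call. = FALSE)
  x <- amplitude * cos(phases)
  if (any(noise_sd > 0)) {
    x <- x + local_seed(seed,
      matrix(stats::rnorm(length(phases), sd = noise_sd), nrow(phases), ncol(phases)))
  }
  x
}
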