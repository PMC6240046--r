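#' Planted network ground truth for the synthetic generator
#'
#' Defines the beta-amplitude correlation structure the simulator plants:
#' parcels fall into modules with correlation `within_module_r` inside a
#' module and `between_module_r` across modules; in the cue condition only,
#' the correlation between the designated seed parcel (the stand-in for
#' early visual cortex) and all parcels of other modules is raised by
#' `seed_cross_boost`, so that the seed parcel's inter-modular integration
#' (participation coefficient) increases during cueing.
#'
#' @param n_parcels Number of parcels.
#' @param n_modules Number of planted modules (parcels split evenly).
#' @param seed_parcel Index of the boosted parcel.
#' @param within_module_r,between_module_r Planted correlations
#'   (`within_module_r > between_module_r`).
#' @param seed_cross_boost Additive correlation increase for
#'   seed-to-other-module pairs, cue condition only.
#' @param voxel_amp_sd SD of voxel-level amplitude noise around the parcel
#'   amplitude (BOLD units).
#' @param noise_sd SD of the scan-level AR(1) measurement noise (BOLD
#'   units).
#' @param ar1_rho Lag-1 autocorrelation of the measurement noise, in
#'   `[0, 1)`.
#' @return A list of class `network_truth` including `parcel_module`, the
#'   parcel-to-module map.
#' @export
network_ground_truth <- function(n_parcels = 115, n_modules = 5,
                                 seed_parcel = 1,
                                 within_module_r = 0.5,
                                 between_module_r = 0.1,
                                 seed_cross_boost = 0.25,
                                 voxel_amp_sd = 0.2,
                                 noise_sd = 1, ar1_rho = 0.3) {
  stopifnot(n_parcels >= 2, n_modules >= 1, n_modules <= n_parcels,
            seed_parcel >= 1, seed_parcel <= n_parcels,
            within_module_r > between_module_r,
            abs(within_module_r) < 1, abs(between_module_r) < 1,
            voxel_amp_sd >= 0, noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1)
  parcel_module <- rep(seq_len(n_modules), length.out = n_parcels)
  parcel_module <- sort(parcel_module)
  truth <- list(n_parcels = n_parcels, n_modules = n_modules,
                parcel_module = parcel_module, seed_parcel = seed_parcel,
                within_module_r = within_module_r,
                between_module_r = between_module_r,
                seed_cross_boost = seed_cross_boost,
                voxel_amp_sd = voxel_amp_sd,
                noise_sd = noise_sd, ar1_rho = ar1_rho)
  class(truth) <- "network_truth"
  truth
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps` and the
#' matrix reassembled (then rescaled to unit diagonal when `correlation`).
#'
#' @param S Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @param correlation Rescale result to unit diagonal.
#' @return Positive-definite matrix.
#' @export
nearest_pd <- function(S, eps = 1e-6, correlation = TRUE) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- (out + t(out)) / 2
  if (correlation) {
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    diag(out) <- 1
  }
  out
}

#' Per-condition planted covariance of parcel beta amplitudes
#'
#' The control-condition matrix is the modular correlation structure; the
#' cue-condition matrix additionally boosts the seed parcel's correlations
#' with all parcels in other modules by `seed_cross_boost`, projected back
#' to the nearest positive-definite correlation matrix if the boost breaks
#' definiteness. This matrix is the sampling oracle for
#' [generate_bold()].
#'
#' @param truth A [network_ground_truth()].
#' @param condition `"cue"` or `"control"`.
#' @return `n_parcels x n_parcels` positive-definite matrix.
#' @export
condition_covariance <- function(truth, condition = c("cue", "control")) {
  condition <- match.arg(condition)
  mods <- truth$parcel_module
  same <- outer(mods, mods, "==")
  S <- ifelse(same, truth$within_module_r, truth$between_module_r)
  diag(S) <- 1
  if (condition == "cue" && truth$seed_cross_boost != 0) {
    s <- truth$seed_parcel
    other <- mods != mods[s]
    S[s, other] <- pmin(S[s, other] + truth$seed_cross_boost, 0.99)
    S[other, s] <- S[s, other]
  }
  S <- nearest_pd(S, eps = 1e-6, correlation = TRUE)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("planted covariance is not positive definite after projection")
  }
  S
}

#' Draw parcel beta amplitudes from the planted model
#'
#' @param truth A [network_ground_truth()].
#' @param condition `"cue"` or `"control"`.
#' @param n_trials Number of trials to draw.
#' @return `n_trials x n_parcels` matrix of amplitudes (unit marginal SD).
#' @export
draw_amplitudes <- function(truth, condition, n_trials) {
  S <- condition_covariance(truth, condition)
  L <- chol(S)
  Z <- matrix(stats::rnorm(n_trials * truth$n_parcels), n_trials)
  Z %*% L
}
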