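#' Simulate an analysis-ready BOLD run for the cueing protocol
#'
#' Per trial, parcel beta amplitudes are drawn from the condition's planted
#' multivariate normal ([condition_covariance()]; the cue condition uses the
#' seed-boosted matrix). Each voxel's amplitude is its parcel's amplitude
#' plus voxel-level noise. The voxel time series is the trial-wise HRF
#' design times these amplitudes, plus a slow cosine drift, linear
#' contributions of six simulated motion and three compartment nuisance
#' series (smooth random walks), and AR(1) measurement noise. The true
#' amplitudes are returned for oracle testing.
#'
#' @param events A `trial_events` data frame from [generate_protocol()]
#'   (attributes `tr` and `n_scans` are used).
#' @param parcellation Integer 3D label array (see
#'   [generate_parcellation()]).
#' @param truth A [network_ground_truth()].
#' @param rng_seed Integer seed.
#' @param drift_scale Amplitude of the slow drift (BOLD units; 0 disables).
#' @param nuisance_scale Amplitude of the simulated nuisance contributions
#'   (0 disables their effect on the data; the nuisance table is still
#'   returned).
#' @return A list of class `bold_sim` with elements `bold` (scans x voxels
#'   matrix, attribute `grid` holding the 3D dims), `nuisance` (scans x 9
#'   data frame, `motion_1..6`, `compartment_1..3`), `truth_betas_voxel`
#'   (voxels x trials), `truth_betas_parcel` (parcels x trials), `events`,
#'   `parcellation`, `truth`.
#' @export
generate_bold <- function(events, parcellation, truth, rng_seed = 1,
                          drift_scale = 1, nuisance_scale = 1) {
  stopifnot(inherits(events, "trial_events"), inherits(truth, "network_truth"))
  tr <- attr(events, "tr"); n_scans <- attr(events, "n_scans")
  if (is.null(tr) || is.null(n_scans)) {
    stop("events must carry tr and n_scans attributes")
  }
  if (max(events$onset + events$duration) > n_scans * tr) {
    stop("events extend past the end of the run")
  }
  grid <- dim(parcellation)
  labels <- as.integer(parcellation)
  if (max(labels) != truth$n_parcels || any(tabulate(labels, truth$n_parcels) == 0)) {
    stop("parcellation labels do not match truth$n_parcels")
  }
  nv <- length(labels)
  n_trials <- nrow(events)
  set.seed(as.integer(rng_seed))

  # per-condition amplitude draws, interleaved back into trial order
  B_parcel <- matrix(0, n_trials, truth$n_parcels)
  for (cond in unique(events$trial_type)) {
    rows <- which(events$trial_type == cond)
    B_parcel[rows, ] <- draw_amplitudes(truth, cond, length(rows))
  }
  B_voxel <- B_parcel[, labels, drop = FALSE] +
    matrix(stats::rnorm(n_trials * nv, 0, truth$voxel_amp_sd), n_trials)

  X <- trial_regressors(events, tr, n_scans)
  Y <- X %*% B_voxel

  # slow drift: random low-frequency cosines (removed by the high-pass)
  if (drift_scale > 0) {
    ndrift <- 3L
    D <- dct_basis(n_scans, tr, cutoff = n_scans * tr / 1.5)[, seq_len(ndrift),
                                                            drop = FALSE]
    Y <- Y + D %*% matrix(stats::rnorm(ndrift * nv, 0, drift_scale), ndrift)
  }

  # nuisance: smooth random walks (cumulated noise, lightly smoothed)
  walk <- function(sd_step) {
    w <- cumsum(stats::rnorm(n_scans, 0, sd_step))
    as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE))
  }
  nuis <- cbind(vapply(1:6, function(i) walk(0.05), numeric(n_scans)),
                vapply(1:3, function(i) walk(0.05), numeric(n_scans)))
  colnames(nuis) <- c(paste0("motion_", 1:6), paste0("compartment_", 1:3))
  if (nuisance_scale > 0) {
    load <- matrix(stats::rnorm(9 * nv, 0, nuisance_scale), 9)
    Y <- Y + nuis %*% load
  }

  # AR(1) measurement noise with marginal SD noise_sd
  if (truth$noise_sd > 0) {
    innov_sd <- truth$noise_sd * sqrt(1 - truth$ar1_rho^2)
    E <- matrix(stats::rnorm(n_scans * nv, 0, innov_sd), n_scans)
    if (truth$ar1_rho > 0) {
      E <- apply(E, 2, function(e)
        as.numeric(stats::filter(e, truth$ar1_rho, method = "recursive")))
    }
    Y <- Y + E
  }

  attr(Y, "grid") <- grid
  out <- list(bold = Y, nuisance = as.data.frame(nuis),
              truth_betas_voxel = t(B_voxel),
              truth_betas_parcel = t(B_parcel),
              events = events, parcellation = parcellation, truth = truth)
  class(out) <- "bold_sim"
  out
}

# scans x trials matrix of HRF-convolved boxcar regressors
trial_regressors <- function(events, tr, n_scans, oversample = 16) {
  dt <- tr / oversample
  t_end <- n_scans * tr
  fine_n <- ceiling(t_end / dt) + 1L
  fine_t <- (seq_len(fine_n) - 1) * dt
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  scan_idx <- round((0:(n_scans - 1)) * tr / dt) + 1L
  X <- matrix(0, n_scans, nrow(events))
  for (k in seq_len(nrow(events))) {
    box <- as.numeric(fine_t >= events$onset[k] &
                        fine_t < events$onset[k] + events$duration[k])
    if (all(box == 0)) box[which.min(abs(fine_t - events$onset[k]))] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(fine_n)] * dt
    X[, k] <- conv[scan_idx]
  }
  colnames(X) <- paste0("trial_", seq_len(nrow(events)))
  X
}
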