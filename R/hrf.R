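#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking near `delay` seconds
#' minus a scaled gamma density modelling the late undershoot. The returned
#' values are scaled so the peak response equals 1.
#'
#' @param t Numeric vector of times in seconds (values outside
#'   `[0, length_s]` evaluate to 0).
#' @param delay Peak delay of the response gamma (seconds).
#' @param undershoot Peak delay of the undershoot gamma (seconds).
#' @param dispersion,u_dispersion Dispersion (scale) of the two gammas.
#' @param ratio Response/undershoot amplitude ratio (undershoot weight is
#'   `1/ratio` relative to the response; default 6 gives the usual 1/6).
#' @param length_s Support of the kernel in seconds.
#' @return Numeric vector, same length as `t`.
#' @export
canonical_hrf <- function(t, delay = 6, undershoot = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 6, length_s = 32) {
  stopifnot(delay > 0, undershoot > 0, dispersion > 0, u_dispersion > 0,
            ratio > 0, length_s > 0)
  h <- numeric(length(t))
  ok <- t >= 0 & t <= length_s
  tt <- t[ok]
  h[ok] <- stats::dgamma(tt, shape = delay / dispersion, scale = dispersion) -
    stats::dgamma(tt, shape = undershoot / u_dispersion, scale = u_dispersion) / ratio
  # normalise to unit peak on a fine grid so regressor scale is interpretable
  grid <- seq(0, length_s, by = 0.01)
  peak <- max(stats::dgamma(grid, shape = delay / dispersion, scale = dispersion) -
                stats::dgamma(grid, shape = undershoot / u_dispersion,
                              scale = u_dispersion) / ratio)
  h / peak
}

#' Discrete cosine high-pass basis
#'
#' Returns the DCT basis functions with period longer than `cutoff` removed
#' by regression, i.e. the `floor(2 * T / cutoff)` lowest-frequency
#' non-constant cosine terms for a run of `n_scans * tr = T` seconds.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cut-off period in seconds.
#' @return Matrix `n_scans x K` (possibly 0 columns), columns named
#'   `dct_1 ... dct_K`.
#' @export
dct_basis <- function(n_scans, tr, cutoff = 128) {
  stopifnot(n_scans >= 2, tr > 0, cutoff > 0)
  T_run <- n_scans * tr
  K <- floor(2 * T_run / cutoff)
  K <- min(K, n_scans - 1)
  n <- 0:(n_scans - 1)
  B <- matrix(0, n_scans, K)
  for (k in seq_len(K)) {
    B[, k] <- sqrt(2 / n_scans) * cos(pi * (2 * n + 1) * k / (2 * n_scans))
  }
  if (K > 0) colnames(B) <- paste0("dct_", seq_len(K))
  B
}
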