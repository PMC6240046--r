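#' Build a trial-wise (beta-series) design matrix
#'
#' One regressor per sound presentation: a boxcar of the event's duration at
#' its onset, convolved with the canonical double-gamma HRF and sampled at
#' scan times. Nuisance columns (six motion + three compartment series) are
#' appended unchanged, followed by a discrete-cosine high-pass basis for the
#' given cut-off period and a constant.
#'
#' @param events A `trial_events` data frame.
#' @param tr Repetition time (seconds); defaults to the events' attribute.
#' @param n_scans Number of scans; defaults to the events' attribute.
#' @param nuisance Optional scans x k data frame/matrix of nuisance series.
#' @param cutoff High-pass cut-off period in seconds (default 128); must
#'   exceed `2 * tr`.
#' @return A list of class `design_matrix`: `X` (scans x p), `labels`,
#'   `trial_cols` (indices of trial columns), `tr`, `n_scans`, `cutoff`,
#'   `trial_type`.
#' @export
build_design <- function(events, tr = attr(events, "tr"),
                         n_scans = attr(events, "n_scans"),
                         nuisance = NULL, cutoff = 128) {
  stopifnot(!is.null(tr), !is.null(n_scans), nrow(events) >= 1)
  if (cutoff <= 2 * tr) {
    stop("high-pass cutoff must exceed twice the TR")
  }
  if (anyDuplicated(events$onset)) {
    stop("overlapping identical onsets would make the trial columns rank deficient")
  }
  if (max(events$onset + events$duration) > n_scans * tr) {
    stop("events extend past the end of the run")
  }
  Xtrial <- trial_regressors(events, tr, n_scans)
  parts <- list(Xtrial)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    }
    parts <- c(parts, list(nuisance))
  }
  D <- dct_basis(n_scans, tr, cutoff)
  if (ncol(D) > 0) parts <- c(parts, list(D))
  const <- matrix(1, n_scans, 1, dimnames = list(NULL, "constant"))
  parts <- c(parts, list(const))
  X <- do.call(cbind, parts)
  out <- list(X = X, labels = colnames(X),
              trial_cols = seq_len(ncol(Xtrial)),
              n_dct = ncol(D), tr = tr, n_scans = n_scans, cutoff = cutoff,
              trial_type = events$trial_type)
  class(out) <- "design_matrix"
  out
}

#' Estimate a beta series by trial-wise GLM with optional AR(1) prewhitening
#'
#' Fits all trial regressors in one GLM per node ("least-squares-all").
#' With `ar1 = "estimate"`, each node is first fit by OLS, the lag-1
#' autocorrelation of its residuals is estimated, data and design are
#' prewhitened by the AR(1) transform and the model refit (a single
#' Cochrane-Orcutt iteration). Only trial-column coefficients are returned,
#' in trial order.
#'
#' @param series Node x scan matrix of time series.
#' @param design A [build_design()] object.
#' @param ar1 `"estimate"` (default) or `"none"`.
#' @param rho_bin Nodes are grouped by their AR(1) estimate rounded to this
#'   precision and refit per group (a speed device; set 0 for per-node
#'   refits).
#' @return A list of class `beta_series`: `betas` (node x trial),
#'   `trial_type`, `node_type`, `grid` (3D dims when nodes are voxels, else
#'   `NULL`), `rho` (per-node AR(1) estimates, zero for `ar1 = "none"`).
#' @export
fit_betas <- function(series, design, ar1 = c("estimate", "none"),
                      rho_bin = 0.005) {
  ar1 <- match.arg(ar1)
  stopifnot(inherits(design, "design_matrix"))
  series <- as.matrix(series)
  if (ncol(series) != design$n_scans) {
    stop("series has ", ncol(series), " scans but design expects ",
         design$n_scans)
  }
  X <- design$X
  Yt <- t(series)                      # scans x nodes
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design$labels[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, Yt)             # p x nodes
  rho <- numeric(nrow(series))
  if (ar1 == "estimate") {
    E <- Yt - X %*% coefs
    n <- nrow(E)
    rho <- colSums(E[-1, , drop = FALSE] * E[-n, , drop = FALSE]) /
      colSums(E^2)
    if (any(rho >= 1)) {
      warning("AR(1) estimate >= 1 at ", sum(rho >= 1),
              " node(s); clipped to 0.99")
      rho[rho >= 1] <- 0.99
    }
    rho[rho <= -1] <- -0.99
    rho_g <- if (rho_bin > 0) round(rho / rho_bin) * rho_bin else rho
    for (r in unique(rho_g)) {
      nodes <- which(rho_g == r)
      if (abs(r) < 1e-12) next       # OLS fit already in place
      Yw <- ar1_whiten(Yt[, nodes, drop = FALSE], r)
      Xw <- ar1_whiten(X, r)
      coefs[, nodes] <- qr.coef(qr(Xw), Yw)
    }
  }
  betas <- t(coefs[design$trial_cols, , drop = FALSE])  # node x trial
  dimnames(betas) <- NULL
  out <- list(betas = betas, trial_type = design$trial_type,
              node_type = "voxel", grid = attr(series, "grid"), rho = rho)
  class(out) <- "beta_series"
  out
}

# AR(1) prewhitening transform: y*_1 = sqrt(1 - rho^2) y_1,
# y*_t = y_t - rho y_{t-1}
ar1_whiten <- function(M, rho) {
  n <- nrow(M)
  W <- M - rho * rbind(0, M[-n, , drop = FALSE])
  W[1, ] <- sqrt(1 - rho^2) * M[1, ]
  W
}

#' Split a beta series by trial condition
#'
#' Partitions the trial columns by their condition label, preserving
#' within-condition trial order; the splits together contain every trial
#' exactly once.
#'
#' @param betas A `beta_series`.
#' @param events Optional `trial_events` to take labels from (defaults to
#'   the labels stored in `betas`).
#' @return Named list of `beta_series`, one per condition; conditions with
#'   zero trials are flagged with a warning and returned empty.
#' @export
split_by_condition <- function(betas, events = NULL) {
  stopifnot(inherits(betas, "beta_series"))
  labels <- if (!is.null(events)) events$trial_type else betas$trial_type
  if (length(labels) != ncol(betas$betas)) {
    stop("trial count mismatch between betas and events")
  }
  known <- c("cue", "control")
  if (!all(labels %in% known)) {
    stop("unknown condition label(s): ",
         paste(setdiff(unique(labels), known), collapse = ", "))
  }
  out <- list()
  for (cond in intersect(known, unique(labels))) {
    sel <- labels == cond
    b <- betas
    b$betas <- betas$betas[, sel, drop = FALSE]
    b$trial_type <- labels[sel]
    out[[cond]] <- b
  }
  for (cond in setdiff(known, names(out))) {
    warning("condition '", cond, "' has no trials")
  }
  out
}
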