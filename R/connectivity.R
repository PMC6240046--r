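#' Pairwise beta-series connectivity matrix
#'
#' Pearson correlation of every node pair's beta series over trials, with a
#' zeroed diagonal. The trial count is recorded for later edge-wise
#' significance thresholding.
#'
#' @param betas A `beta_series` (node x trial) or plain node x trial
#'   matrix.
#' @param max_nodes Guard on the node budget of dense voxel-level graphs.
#' @return A list of class `connectivity_graph`: `W` (node x node weights),
#'   `n_trials`, `condition`, `threshold` (`NULL` until thresholded),
#'   `grid`.
#' @export
correlation_matrix <- function(betas, max_nodes = 2000) {
  B <- if (inherits(betas, "beta_series")) betas$betas else as.matrix(betas)
  if (ncol(B) < 3) stop("need at least 3 trials to correlate")
  if (nrow(B) > max_nodes) {
    stop(nrow(B), " nodes exceed the max_nodes budget (", max_nodes,
         "); raise max_nodes to proceed")
  }
  v <- apply(B, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance node(s): ",
         paste(utils::head(which(v == 0), 10), collapse = ", "))
  }
  W <- stats::cor(t(B))
  diag(W) <- 0
  cond <- if (inherits(betas, "beta_series")) {
    u <- unique(betas$trial_type)
    if (length(u) == 1) u else NA_character_
  } else NA_character_
  g <- list(W = W, n_trials = ncol(B), condition = cond, threshold = NULL,
            grid = if (inherits(betas, "beta_series")) betas$grid else NULL)
  class(g) <- "connectivity_graph"
  g
}

#' FDR-threshold a connectivity graph
#'
#' Each unique edge's correlation is converted to a two-sided p-value by the
#' t-transform with `n_trials - 2` degrees of freedom; the Benjamini-
#' Hochberg step-up procedure is applied over all unique edges at level `q`;
#' non-significant edges and all negative correlations are set to zero.
#'
#' @param graph A `connectivity_graph` (unthresholded).
#' @param q FDR level (default 0.05).
#' @return The graph with `W` thresholded and `threshold` recording `q`,
#'   the number of surviving edges, and the BH critical p-value.
#' @export
threshold_fdr <- function(graph, q = 0.05) {
  stopifnot(inherits(graph, "connectivity_graph"))
  n <- graph$n_trials
  if (is.null(n) || n < 4) stop("need n_trials >= 4 to threshold")
  W <- graph$W
  ut <- upper.tri(W)
  r <- W[ut]
  p <- r_to_p(r, n)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- padj <= q & r > 0
  Wt <- matrix(0, nrow(W), ncol(W))
  Wt[ut] <- ifelse(keep, r, 0)
  Wt <- Wt + t(Wt)
  if (!any(keep)) {
    warning("no edges survive FDR thresholding; graph is empty")
  }
  graph$W <- Wt
  graph$threshold <- list(q = q, test = "edgewise t on r, BH step-up",
                          n_edges_kept = sum(keep),
                          critical_p = if (any(keep)) max(p[keep]) else 0)
  graph
}

# two-sided p for Pearson r at n observations (t transform, df = n - 2)
r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
}

#' Average a voxel beta series within parcels
#'
#' Parcel series are unweighted means of their member voxels' beta series;
#' the result has one node per parcel.
#'
#' @param betas A voxel-level `beta_series` (node order = linear voxel
#'   order of the parcellation grid).
#' @param parcellation Integer 3D label array covering every voxel.
#' @return A parcel-level `beta_series`.
#' @export
parcel_average <- function(betas, parcellation) {
  stopifnot(inherits(betas, "beta_series"))
  labels <- as.integer(parcellation)
  if (length(labels) != nrow(betas$betas)) {
    stop("parcellation voxel count does not match beta-series nodes")
  }
  np <- max(labels)
  counts <- tabulate(labels, np)
  if (any(counts == 0)) {
    stop("empty parcel(s): ", paste(which(counts == 0), collapse = ", "))
  }
  M <- matrix(0, np, length(labels))
  M[cbind(labels, seq_along(labels))] <- 1 / counts[labels]
  out <- betas
  out$betas <- M %*% betas$betas
  out$node_type <- "parcel"
  out$grid <- NULL
  class(out) <- "beta_series"
  out
}
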