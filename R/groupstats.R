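#' Paired t map across subjects
#'
#' Node-wise one-sample t-test on the subject differences `maps_a -
#' maps_b`, with two-sided p-values and a z-map obtained by the probit
#' transform of p carrying the sign of t (the usual t-to-z display
#' convention). Nodes whose difference is constant and non-zero across
#' subjects cannot be tested and are flagged `NA` with a warning; nodes
#' with identically zero differences get t = 0.
#'
#' @param maps_a,maps_b Subject x node matrices (matching shapes).
#' @param grid Optional 3D grid dims of the node space (for clustering).
#' @param contrast Description string.
#' @return A list of class `stat_map`: `t`, `z`, `p`, `df`, `n_subjects`,
#'   `subject_diffs` (subject x node, used by permutation inference),
#'   `grid`, `contrast`, `flagged` (indices of untestable nodes).
#' @export
paired_t_map <- function(maps_a, maps_b, grid = NULL, contrast = "a - b") {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  stopifnot(all(dim(maps_a) == dim(maps_b)))
  n <- nrow(maps_a)
  if (n < 3) stop("need at least 3 subjects")
  D <- maps_a - maps_b
  one_sample_t_map(D, grid = grid, contrast = contrast)
}

# one-sample t over the rows of D (subject x node)
one_sample_t_map <- function(D, grid = NULL, contrast = "mean") {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  t_stat <- m / se
  t_stat[se == 0 & m == 0] <- 0
  flagged <- which(se == 0 & m != 0)
  if (length(flagged)) {
    t_stat[flagged] <- NA_real_
    warning(length(flagged),
            " node(s) with zero-variance non-zero differences flagged NA")
  }
  df <- n - 1
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  z <- t_to_z(t_stat, df)
  out <- list(t = t_stat, z = z, p = p, df = df, n_subjects = n,
              subject_diffs = D, grid = grid, contrast = contrast,
              flagged = flagged,
              perm = list(scheme = "signflip", data = D))
  class(out) <- "stat_map"
  out
}

# signed probit transform of the two-sided p, SPM-style t -> z display
t_to_z <- function(t_stat, df) {
  p1 <- stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  z <- stats::qnorm(pmax(p1, 1e-300), lower.tail = FALSE)
  sign(t_stat) * z
}

#' Seed-based connectivity contrast map
#'
#' Per subject and condition, the seed series is the mean beta series over
#' the seed nodes; its Pearson correlation with every other node's beta
#' series is Fisher z-transformed, and the subject contrast is
#' `z(cue) - z(control)`. The group map is the paired t-test of the two
#' Fisher-z maps across subjects. Target nodes inside the seed are excluded
#' (set `NA`) and recorded.
#'
#' @param seed_nodes Integer indices (or logical mask) of the seed nodes.
#' @param betas_by_subject List over subjects; each element a named list
#'   with `cue` and `control` `beta_series` (same node space).
#' @param grid Optional 3D grid dims.
#' @return A `stat_map` with extra elements `subject_contrasts`
#'   (subject x node Fisher-z differences), `z_cue`, `z_control`
#'   (subject x node), `excluded` (seed node indices).
#' @export
seed_contrast_map <- function(seed_nodes, betas_by_subject, grid = NULL) {
  stopifnot(length(betas_by_subject) >= 3)
  first <- betas_by_subject[[1]]$cue
  if (is.null(first)) stop("each subject needs cue and control beta series")
  n_nodes <- nrow(first$betas)
  if (is.logical(seed_nodes)) seed_nodes <- which(seed_nodes)
  if (length(seed_nodes) == 0) stop("empty seed")
  n_sub <- length(betas_by_subject)
  Zc <- matrix(NA_real_, n_sub, n_nodes)
  Zk <- matrix(NA_real_, n_sub, n_nodes)
  for (s in seq_len(n_sub)) {
    bs <- betas_by_subject[[s]]
    if (is.null(bs$cue) || is.null(bs$control)) {
      stop("subject ", s, " is missing a condition")
    }
    Zc[s, ] <- seed_fisher_z(seed_nodes, bs$cue$betas)
    Zk[s, ] <- seed_fisher_z(seed_nodes, bs$control$betas)
  }
  Zc[, seed_nodes] <- 0
  Zk[, seed_nodes] <- 0
  map <- paired_t_map(Zc, Zk, grid = grid,
                      contrast = "seed connectivity: cue - control (Fisher z)")
  map$t[seed_nodes] <- NA_real_
  map$z[seed_nodes] <- NA_real_
  map$p[seed_nodes] <- NA_real_
  map$subject_contrasts <- Zc - Zk
  map$subject_contrasts[, seed_nodes] <- NA_real_
  map$z_cue <- Zc
  map$z_control <- Zk
  map$excluded <- sort(seed_nodes)
  map
}

# Fisher-z correlation of the mean seed series with every node's series
seed_fisher_z <- function(seed_nodes, B) {
  seed <- colMeans(B[seed_nodes, , drop = FALSE])
  r <- suppressWarnings(as.numeric(stats::cor(seed, t(B))))
  r[is.na(r)] <- 0                     # zero-variance nodes: no association
  atanh(pmin(pmax(r, -0.999999), 0.999999))
}

#' Covariate (simple-regression slope) map
#'
#' Node-wise t-statistic of the slope from regressing subject contrast
#' values on a mean-centred covariate (a second-level GLM with one
#' covariate), with `n - 2` degrees of freedom. Noiseless exact fits give
#' infinite t; those nodes are capped at `t_cap` and flagged.
#'
#' @param contrast_maps Subject x node matrix.
#' @param covariate Numeric vector, one value per subject; must vary.
#' @param grid Optional 3D grid dims.
#' @param t_cap Cap applied to infinite t-statistics.
#' @return A `stat_map` with extra elements `slope` and `capped` (indices
#'   of capped nodes); `subject_diffs` holds covariate-projected maps used
#'   by permutation inference.
#' @export
covariate_map <- function(contrast_maps, covariate, grid = NULL,
                          t_cap = 38.5) {
  C <- as.matrix(contrast_maps)
  n <- nrow(C)
  if (n < 4) stop("need at least 4 subjects")
  if (length(covariate) != n) stop("one covariate value per subject required")
  x <- covariate - mean(covariate)
  sxx <- sum(x^2)
  if (sxx == 0) stop("covariate is constant")
  slope <- as.numeric(crossprod(x, C)) / sxx
  fitted <- outer(x, slope) + matrix(colMeans(C), n, ncol(C), byrow = TRUE)
  rss <- colSums((C - fitted)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  t_stat <- slope / se
  capped <- which(!is.finite(t_stat) & se == 0 & slope != 0)
  t_stat[se == 0 & slope == 0] <- 0
  t_stat[capped] <- sign(slope[capped]) * t_cap
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  z <- t_to_z(t_stat, df)
  out <- list(t = t_stat, z = z, p = p, df = df, n_subjects = n,
              slope = slope, capped = capped,
              grid = grid, contrast = "covariate slope",
              perm = list(scheme = "covariate", data = C, x = x))
  class(out) <- "stat_map"
  out
}
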