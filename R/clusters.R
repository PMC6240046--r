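#' Cluster-extent inference on a statistic map
#'
#' Thresholds the z-map at `z_threshold` (one-sided, in the map's positive
#' direction; negative clusters can be obtained by negating the map) and
#' extracts maximal face-connected suprathreshold clusters on the 3D grid.
#' Corrected cluster p-values come from either
#' \describe{
#'   \item{permutation}{the max-cluster-extent null distribution over
#'     `n_perm` random sign flips of the subject-level difference maps
#'     (or random permutations of the covariate for covariate maps);
#'     `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.}
#'   \item{grf}{a Gaussian-random-field RESEL-based approximation using a
#'     residual smoothness estimate. This is a closed-form approximation
#'     (documented as such); permutation is the primary method.}
#' }
#'
#' @param map A `stat_map` with a `grid` (3D dims).
#' @param z_threshold Cluster-forming threshold on the z scale (default
#'   2.33).
#' @param method `"permutation"` (default) or `"grf"`.
#' @param n_perm Number of permutations (>= 100).
#' @param rng_seed Integer seed for the permutation draws.
#' @param mask Optional logical array/vector restricting the analysis.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @param fwhm Optional smoothness (FWHM in voxels) for `"grf"`; estimated
#'   from the subject residual maps when `NULL`.
#' @return A `data.frame` with one row per cluster: `cluster`, `extent`,
#'   `peak_stat` (peak z), `peak_index` (linear voxel index), `peak_x/y/z`
#'   (voxel coordinates), `p_corrected`; attribute `voxels` holds the
#'   member-voxel indices per cluster, attribute `null_max_extent` the
#'   permutation null (permutation method only). Zero rows when nothing
#'   survives the threshold.
#' @export
cluster_inference <- function(map, z_threshold = 2.33,
                              method = c("permutation", "grf"),
                              n_perm = 999, rng_seed = 1, mask = NULL,
                              connectivity = 6, fwhm = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(map, "stat_map"))
  grid <- map$grid
  if (is.null(grid) || length(grid) != 3) {
    stop("map must carry 3D grid dims for cluster inference")
  }
  nv <- prod(grid)
  stopifnot(length(map$z) == nv)
  mask_vec <- if (is.null(mask)) rep(TRUE, nv) else as.logical(mask)
  stopifnot(length(mask_vec) == nv)

  z <- map$z
  z[!mask_vec | is.na(z)] <- -Inf
  supra <- which(z > z_threshold)
  clus <- label_clusters(supra, grid, connectivity)
  res <- cluster_table(clus, z, grid)
  if (nrow(res) == 0) {
    attr(res, "voxels") <- list()
    return(res)
  }

  if (method == "permutation") {
    if (n_perm < 100) stop("need n_perm >= 100")
    if (is.null(map$perm)) {
      stop("permutation inference needs subject-level maps in the stat map")
    }
    t_thr <- z_to_t(z_threshold, map$df)
    null_max <- perm_null_max_extent(map, t_thr, n_perm, rng_seed,
                                     mask_vec, grid, connectivity)
    res$p_corrected <- vapply(res$extent, function(k)
      (1 + sum(null_max >= k)) / (1 + n_perm), numeric(1))
    attr(res, "null_max_extent") <- null_max
  } else {
    if (is.null(fwhm)) {
      if (is.null(map$subject_diffs)) {
        stop("grf smoothness estimation needs subject-level maps; supply fwhm")
      }
      fwhm <- estimate_fwhm(map$subject_diffs, grid)
    }
    S <- sum(mask_vec)
    res$p_corrected <- vapply(res$extent, function(k)
      grf_cluster_p(k, z_threshold, S, fwhm), numeric(1))
  }
  res
}

# map a one-sided z threshold to the matching t threshold (same tail mass)
z_to_t <- function(z, df) {
  stats::qt(stats::pnorm(z, lower.tail = FALSE), df = df, lower.tail = FALSE)
}

# label face/edge/corner-connected components among suprathreshold voxels;
# returns a list of integer vectors (member linear indices)
label_clusters <- function(supra, grid, connectivity = 6) {
  if (length(supra) == 0) return(list())
  offs <- connectivity_offsets(connectivity)
  nx <- grid[1]; ny <- grid[2]
  x <- (supra - 1L) %% nx
  y <- ((supra - 1L) %/% nx) %% ny
  z <- (supra - 1L) %/% (nx * ny)
  elist <- vector("list", nrow(offs))
  for (j in seq_len(nrow(offs))) {
    xo <- x + offs[j, 1]; yo <- y + offs[j, 2]; zo <- z + offs[j, 3]
    ok <- xo >= 0 & xo < grid[1] & yo >= 0 & yo < grid[2] &
      zo >= 0 & zo < grid[3]
    nb <- 1L + xo[ok] + nx * (yo[ok] + ny * zo[ok])
    hit <- match(nb, supra)
    sel <- !is.na(hit)
    if (any(sel)) {
      elist[[j]] <- cbind(which(ok)[sel], hit[sel])
    }
  }
  edges <- do.call(rbind, elist)
  n <- length(supra)
  if (is.null(edges)) {
    comp <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  split(supra, comp)
}

connectivity_offsets <- function(connectivity) {
  all_offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  all_offs <- all_offs[rowSums(abs(all_offs)) > 0, , drop = FALSE]
  d <- rowSums(abs(all_offs))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = d <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  all_offs[keep, , drop = FALSE]
}

cluster_table <- function(clus, z, grid) {
  if (length(clus) == 0) {
    res <- data.frame(cluster = integer(0), extent = integer(0),
                      peak_stat = numeric(0), peak_index = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), p_corrected = numeric(0))
    return(res)
  }
  clus <- clus[order(-vapply(clus, length, 1L))]
  nx <- grid[1]; ny <- grid[2]
  rows <- lapply(seq_along(clus), function(i) {
    vox <- clus[[i]]
    pk <- vox[which.max(z[vox])]
    data.frame(cluster = i, extent = length(vox), peak_stat = z[pk],
               peak_index = pk,
               peak_x = (pk - 1L) %% nx + 1L,
               peak_y = ((pk - 1L) %/% nx) %% ny + 1L,
               peak_z = (pk - 1L) %/% (nx * ny) + 1L,
               p_corrected = NA_real_)
  })
  res <- do.call(rbind, rows)
  attr(res, "voxels") <- clus
  res
}

# max suprathreshold cluster extent per permutation, vectorised per scheme
perm_null_max_extent <- function(map, t_thr, n_perm, rng_seed, mask_vec,
                                 grid, connectivity) {
  set.seed(as.integer(rng_seed))
  scheme <- map$perm$scheme
  if (scheme == "signflip") {
    D <- map$perm$data
    D[is.na(D)] <- 0
    n <- nrow(D)
    ss <- colSums(D^2)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Sums <- signs %*% D                         # n_perm x nodes
    m <- Sums / n
    s2 <- (matrix(ss, n_perm, length(ss), byrow = TRUE) - n * m^2) / (n - 1)
    Tp <- m / sqrt(pmax(s2, .Machine$double.eps) / n)
  } else if (scheme == "covariate") {
    C <- map$perm$data
    C[is.na(C)] <- 0
    x <- map$perm$x
    n <- nrow(C)
    sxx <- sum(x^2)
    syy <- colSums(C^2) - n * colMeans(C)^2
    P <- t(vapply(seq_len(n_perm), function(i) sample(x), numeric(length(x))))
    slopes <- (P %*% C) / sxx                  # n_perm x nodes
    df <- n - 2
    denom <- sweep(-(slopes^2) * sxx, 2, syy, "+")
    Tp <- slopes * sqrt(sxx) * sqrt(df) / sqrt(pmax(denom, .Machine$double.eps))
  } else {
    stop("unknown permutation scheme: ", scheme)
  }
  Tp[, !mask_vec] <- -Inf
  apply(Tp, 1, function(tv) {
    supra <- which(tv > t_thr)
    if (length(supra) == 0) return(0L)
    max(vapply(label_clusters(supra, grid, connectivity), length, 1L))
  })
}

# residual smoothness (FWHM in voxels, geometric mean over axes) from
# normalised subject residual maps, via the variance of spatial derivatives
estimate_fwhm <- function(subject_maps, grid) {
  R <- as.matrix(subject_maps)
  R[is.na(R)] <- 0
  R <- sweep(R, 2, colMeans(R))
  sdv <- sqrt(colSums(R^2))
  sdv[sdv == 0] <- 1
  R <- sweep(R, 2, sdv, "/")
  fw <- numeric(3)
  for (ax in 1:3) {
    d2 <- 0; cnt <- 0
    for (s in seq_len(nrow(R))) {
      A <- array(R[s, ], dim = grid)
      dd <- switch(ax,
                   A[-1, , , drop = FALSE] - A[-grid[1], , , drop = FALSE],
                   A[, -1, , drop = FALSE] - A[, -grid[2], , drop = FALSE],
                   A[, , -1, drop = FALSE] - A[, , -grid[3], drop = FALSE])
      d2 <- d2 + sum(dd^2); cnt <- cnt + length(dd)
    }
    lambda <- d2 / cnt / 2              # var of derivative / 2 = lambda
    fw[ax] <- sqrt(4 * log(2) / pmax(2 * lambda, 1e-12))
  }
  exp(mean(log(fw)))
}

# GRF closed-form corrected cluster p (approximate): expected number of
# clusters Em from the EC density, exponential approximation for extents
grf_cluster_p <- function(extent, u, n_vox, fwhm) {
  resels <- n_vox / fwhm^3
  rho3 <- (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  Em <- pmax(resels * rho3, 1e-12)
  nbar <- n_vox * stats::pnorm(u, lower.tail = FALSE) / Em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  p_ext <- exp(-beta * extent^(2 / 3))
  1 - exp(-Em * p_ext)
}

#' Benjamini-Hochberg critical p-value
#'
#' Step-up critical value: the largest sorted `p_(i)` with
#' `p_(i) <= i * q / m`, or 0 when no p-value passes.
#'
#' @param p Numeric vector of p-values.
#' @param q FDR level.
#' @return Scalar critical p.
#' @export
bh_critical_p <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  ps <- sort(p)
  ok <- ps <= seq_len(m) * q / m
  if (!any(ok)) return(0)
  ps[max(which(ok))]
}

#' Small-volume correction with FDR across regions of interest
#'
#' Runs [cluster_inference()] restricted to each ROI mask, takes the
#' minimum corrected cluster p per ROI (1 when no cluster forms), and
#' applies the Benjamini-Hochberg procedure across the ROI p-values at
#' level `q` to obtain the critical p-value and per-ROI significance.
#'
#' @param map A `stat_map` on a 3D grid.
#' @param roi_masks Named list of logical arrays/vectors (one per ROI).
#' @param z_threshold Cluster-forming threshold.
#' @param q FDR level across ROIs.
#' @param method,n_perm,rng_seed,connectivity Passed to
#'   [cluster_inference()].
#' @return A list of class `roi_correction`: `table` (data frame with
#'   `roi`, `p`, `significant`), `critical_p`, `q`.
#' @export
small_volume_correct <- function(map, roi_masks, z_threshold = 2.33,
                                 q = 0.05, method = "permutation",
                                 n_perm = 999, rng_seed = 1,
                                 connectivity = 6) {
  stopifnot(length(roi_masks) >= 1, !is.null(names(roi_masks)))
  p_roi <- numeric(length(roi_masks))
  for (i in seq_along(roi_masks)) {
    mask <- as.logical(roi_masks[[i]])
    if (!any(mask)) stop("empty ROI mask: ", names(roi_masks)[i])
    ci <- cluster_inference(map, z_threshold = z_threshold, method = method,
                            n_perm = n_perm, rng_seed = rng_seed,
                            mask = mask, connectivity = connectivity)
    p_roi[i] <- if (nrow(ci) == 0) 1 else min(ci$p_corrected)
  }
  crit <- bh_critical_p(p_roi, q)
  out <- list(table = data.frame(roi = names(roi_masks), p = p_roi,
                                 significant = crit > 0 & p_roi <= crit,
                                 stringsAsFactors = FALSE),
              critical_p = crit, q = q)
  class(out) <- "roi_correction"
  out
}
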