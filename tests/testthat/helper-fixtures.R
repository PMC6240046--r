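# shared fixtures and independent oracles (kept deliberately naive:
# every oracle recomputes its quantity by direct enumeration)

# wrap a plain weight matrix as a connectivity graph with a trial count
as_graph <- function(W, n_trials = 50) {
  g <- list(W = W, n_trials = n_trials, condition = NA_character_,
            threshold = NULL, grid = NULL)
  class(g) <- "connectivity_graph"
  g
}

# wrap a node x trial matrix as a beta series
as_betas <- function(B, trial_type = rep("cue", ncol(B)), grid = NULL) {
  b <- list(betas = B, trial_type = trial_type, node_type = "voxel",
            grid = grid, rho = NULL)
  class(b) <- "beta_series"
  b
}

# random connected-ish non-negative weighted graph
random_weighted_graph <- function(n, p_edge = 0.3) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  on <- ut & matrix(stats::runif(n * n) < p_edge, n, n)
  W[on] <- stats::runif(sum(on), 0.1, 1)
  W + t(W)
}

# brute-force participation coefficient: explicit per-module summation
pc_oracle <- function(W, labels) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ])
    if (k == 0) next
    acc <- 0
    for (s in unique(labels)) {
      acc <- acc + (sum(W[i, labels == s]) / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# brute-force modularity: explicit double sum over node pairs
modularity_oracle <- function(W, membership, gamma = 1) {
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# independent step-up FDR enumeration (Benjamini-Hochberg definition)
bh_survivors_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  passes <- which(p[ord] <= seq_len(m) * q / m)
  if (length(passes) == 0) return(logical(m))
  kmax <- max(passes)
  out <- logical(m)
  out[ord[seq_len(kmax)]] <- TRUE
  out
}

# brute-force Kendall tau-b via O(n^2) pair enumeration
kendall_oracle <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  S / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# correlation value whose edgewise two-sided p equals `p` at n trials
r_for_p <- function(p, n) {
  t_val <- stats::qt(p / 2, df = n - 2, lower.tail = FALSE)
  t_val / sqrt(t_val^2 + n - 2)
}

# nv x nv Gaussian smoothing matrix for a 3D grid (separable kernel)
smoothing_matrix <- function(grid, fwhm = 2) {
  g1 <- function(n) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    K <- outer(seq_len(n), seq_len(n), function(i, j) stats::dnorm(i - j, 0, s))
    K / rowSums(K)
  }
  kronecker(g1(grid[3]), kronecker(g1(grid[2]), g1(grid[1])))
}

# parcel contiguity check by flood fill on the 6-connected lattice
parcel_is_contiguous <- function(parc, label) {
  idx <- which(parc == label)
  if (length(idx) <= 1) return(TRUE)
  grid <- dim(parc)
  coord <- arrayInd(idx, grid)
  visited <- logical(length(idx))
  visited[1] <- TRUE
  frontier <- 1
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (f in frontier) {
      d <- abs(coord[, 1] - coord[f, 1]) + abs(coord[, 2] - coord[f, 2]) +
        abs(coord[, 3] - coord[f, 3])
      hit <- which(d == 1 & !visited)
      visited[hit] <- TRUE
      nxt <- c(nxt, hit)
    }
    frontier <- nxt
  }
  all(visited)
}

# linear voxel indices for all combinations of grid coordinates
ind3 <- function(x, y, z, grid) {
  co <- expand.grid(x = x, y = y, z = z)
  as.integer(co$x + grid[1] * (co$y - 1) + grid[1] * grid[2] * (co$z - 1))
}

# probe the (internal) GRF cluster p approximation
grf_p_probe <- function(extent, u = 2.33, n_vox = 1728, fwhm = 2.5) {
  tmrnet:::grf_cluster_p(extent, u, n_vox, fwhm)
}

# tiny protocol for fast GLM tests
small_protocol <- function(n_scans = 70, tr = 2) {
  protocol_spec(n_cue_sounds = 2, cue_repetitions = 2, n_control_sounds = 2,
                control_repetitions = 2, block_size = 2, tr = tr,
                n_scans = n_scans, isi_range = c(8, 14))
}
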