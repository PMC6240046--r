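#' Generate a synthetic contiguous parcellation
#'
#' Grows `n_parcels` spatially contiguous parcels from randomly placed seed
#' voxels by multi-source breadth-first region growing on the 6-connected
#' voxel lattice, emulating an anatomical atlas (e.g. a 115-region AAL-style
#' parcellation) at desk scale.
#'
#' @param grid_shape Integer length-3, voxel grid dimensions.
#' @param n_parcels Number of parcels (labels `1..n_parcels`).
#' @param rng_seed Integer seed; output is deterministic given the seed.
#' @return Integer 3D array of parcel labels; every voxel labelled, every
#'   parcel non-empty and contiguous.
#' @export
generate_parcellation <- function(grid_shape = c(12, 12, 12), n_parcels = 115,
                                  rng_seed = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), n_parcels >= 1)
  nv <- prod(grid_shape)
  if (n_parcels > nv) {
    stop(sprintf("n_parcels (%d) exceeds voxel count (%d)", n_parcels, nv))
  }
  set.seed(as.integer(rng_seed))
  labels <- integer(nv)
  seeds <- sample(nv, n_parcels)
  labels[seeds] <- seq_len(n_parcels)
  nbr <- grid_neighbours(grid_shape)
  frontier <- seeds
  while (length(frontier) > 0) {
    # candidate assignments: unlabelled neighbours of the frontier
    cand_from <- rep(frontier, vapply(nbr[frontier], length, 1L))
    cand_to <- unlist(nbr[frontier], use.names = FALSE)
    keep <- labels[cand_to] == 0L
    cand_from <- cand_from[keep]; cand_to <- cand_to[keep]
    if (length(cand_to) == 0) break
    ord <- sample(length(cand_to))
    cand_from <- cand_from[ord]; cand_to <- cand_to[ord]
    first <- !duplicated(cand_to)
    labels[cand_to[first]] <- labels[cand_from[first]]
    frontier <- cand_to[first]
  }
  if (any(labels == 0L)) stop("region growing failed to cover the grid")
  array(labels, dim = grid_shape)
}

# neighbour list (6-connectivity) for every voxel of a 3D grid,
# as linear indices
grid_neighbours <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  nv <- nx * ny * nz
  idx <- seq_len(nv)
  x <- (idx - 1L) %% nx
  y <- ((idx - 1L) %/% nx) %% ny
  z <- (idx - 1L) %/% (nx * ny)
  res <- vector("list", nv)
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(NA_integer_, nv, 6)
  for (j in seq_along(offs)) {
    xo <- x + offs[[j]][1]; yo <- y + offs[[j]][2]; zo <- z + offs[[j]][3]
    ok <- xo >= 0 & xo < nx & yo >= 0 & yo < ny & zo >= 0 & zo < nz
    nb[ok, j] <- 1L + xo[ok] + nx * (yo[ok] + ny * zo[ok])
  }
  for (i in idx) res[[i]] <- nb[i, !is.na(nb[i, ])]
  res
}

#' Default bundled synthetic atlas
#'
#' The package's reference parcellation: 115 contiguous parcels on a
#' 12 x 12 x 12 grid, generated from a fixed seed so every session sees the
#' same atlas.
#'
#' @return Integer 3D label array.
#' @export
default_parcellation <- function() {
  generate_parcellation(c(12, 12, 12), 115, rng_seed = 115)
}
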