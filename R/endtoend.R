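#' Run the single-subject analysis chain in memory
#'
#' Convenience wrapper chaining the per-subject stages without file IO:
#' trial-wise GLM (AR(1) prewhitened), condition split, coarse
#' parcel-level graph -> Louvain modules, then voxel-level FDR-thresholded
#' graph -> participation-coefficient map, per condition.
#'
#' @param sim A [generate_bold()] result.
#' @param q Edge FDR level.
#' @param gamma Louvain resolution.
#' @param n_restarts Louvain restarts.
#' @param rng_seed Seed for the Louvain restarts.
#' @param ar1 Prewhitening mode for [fit_betas()].
#' @param cutoff High-pass cut-off (seconds).
#' @return A list per condition (`cue`, `control`), each with `pc` (voxel
#'   participation coefficients), `partition` (parcel `module_partition`),
#'   `betas` (voxel `beta_series`); plus `grid`.
#' @export
analyze_subject <- function(sim, q = 0.05, gamma = 1, n_restarts = 100,
                            rng_seed = 1, ar1 = "estimate", cutoff = 128) {
  stopifnot(inherits(sim, "bold_sim"))
  des <- build_design(sim$events, nuisance = sim$nuisance, cutoff = cutoff)
  bs <- fit_betas(t(sim$bold), des, ar1 = ar1)
  bs$grid <- attr(sim$bold, "grid")
  splits <- split_by_condition(bs)
  out <- list(grid = bs$grid)
  for (cond in names(splits)) {
    coarse <- parcel_average(splits[[cond]], sim$parcellation)
    g_coarse <- threshold_fdr(correlation_matrix(coarse), q = q)
    part <- louvain_partition(g_coarse, gamma = gamma,
                              n_restarts = n_restarts, rng_seed = rng_seed)
    vox_labels <- propagate_modules(part, sim$parcellation)
    g_fine <- threshold_fdr(
      correlation_matrix(splits[[cond]],
                         max_nodes = max(2000, nrow(splits[[cond]]$betas))),
      q = q)
    pc <- participation_coefficient(g_fine, vox_labels)
    out[[cond]] <- list(pc = pc, partition = part, betas = splits[[cond]])
  }
  out
}
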