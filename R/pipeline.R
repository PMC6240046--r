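#' Pipeline run configuration
#'
#' Collects every parameter and per-stage RNG seed of the end-to-end
#' pipeline (simulate -> betas -> graph -> group -> behavior). All
#' stochastic stages draw from explicit seeds derived from `seed`, so a
#' rerun with the same configuration is bit-identical for deterministic
#' stages.
#'
#' @param workdir Directory that receives all stage outputs and manifests.
#' @param n_subjects Number of simulated subjects.
#' @param grid 3D voxel grid dimensions.
#' @param n_parcels Number of atlas parcels.
#' @param seed Master integer seed; per-stage seeds are derived from it
#'   (override via `seeds`).
#' @param protocol Named list of [protocol_spec()] overrides.
#' @param truth Named list of [network_ground_truth()] overrides.
#' @param behavior Named list of [generate_behavior()] overrides.
#' @param analysis Named list of analysis parameters: `q` (edge FDR),
#'   `z_threshold`, `gamma`, `n_restarts`, `n_perm`, `connectivity`,
#'   `cutoff` (high-pass seconds), `ar1` (`"estimate"`/`"none"`),
#'   `n_rois_seed`, `n_rois_covariate`.
#' @param seeds Optional named list overriding the derived per-stage seeds
#'   (`simulate`, `graph`, `group`).
#' @param verbosity 0 = silent, 1 = stage messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(workdir = tempfile("tmrnet_run_"), n_subjects = 6,
                       grid = c(12, 12, 12), n_parcels = 115, seed = 1,
                       protocol = list(), truth = list(), behavior = list(),
                       analysis = list(), seeds = list(), verbosity = 1) {
  ana <- utils::modifyList(
    list(q = 0.05, z_threshold = 2.33, gamma = 1, n_restarts = 100,
         n_perm = 199, connectivity = 6, cutoff = 128, ar1 = "estimate"),
    analysis)
  sd <- utils::modifyList(
    list(simulate = seed + 101L, graph = seed + 202L, group = seed + 303L),
    seeds)
  cfg <- list(workdir = workdir, n_subjects = n_subjects,
              grid = as.integer(grid), n_parcels = n_parcels, seed = seed,
              protocol = protocol, truth = truth, behavior = behavior,
              analysis = ana, seeds = sd, verbosity = verbosity)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (YAML or JSON)
#'
#' @param cfg A `run_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config` returns a `run_config` identical to the one
#'   written.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- run_config(workdir = x$workdir, n_subjects = x$n_subjects,
                    grid = x$grid, n_parcels = x$n_parcels, seed = x$seed,
                    protocol = as.list(x$protocol), truth = as.list(x$truth),
                    behavior = as.list(x$behavior),
                    analysis = as.list(x$analysis),
                    seeds = as.list(x$seeds), verbosity = x$verbosity)
  cfg
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("config must be a run_config")
  for (f in c("workdir", "n_subjects", "grid", "n_parcels", "seed")) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  }
  if (cfg$n_subjects < 2) stop("config: n_subjects must be >= 2")
  if (length(cfg$grid) != 3) stop("config: grid must have 3 dims")
  for (f in c("q", "z_threshold", "n_perm")) {
    if (is.null(cfg$analysis[[f]])) stop("config field missing: analysis$", f)
  }
  invisible(TRUE)
}

#' Run one pipeline stage (or all)
#'
#' Stages: `simulate` (synthetic events, BOLD, parcellation, behavior),
#' `betas` (trial-wise GLM -> condition beta series), `graph` (coarse
#' modules + voxel participation-coefficient maps per condition), `group`
#' (paired PC contrast with permutation cluster correction, seed-based
#' connectivity contrast with small-volume FDR correction, covariate map),
#' `behavior` (forgetting summary and brain-behavior statistics), `all`
#' (chain). Each stage writes its outputs plus a JSON manifest recording
#' parameters, seed and content hashes of inputs and outputs.
#'
#' @param stage One of `"simulate"`, `"betas"`, `"graph"`, `"group"`,
#'   `"behavior"`, `"all"`.
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest of the (last) stage run.
#' @export
run_stage <- function(stage = c("simulate", "betas", "graph", "group",
                                "behavior", "all"), cfg) {
  stage <- match.arg(stage)
  validate_config(cfg)
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "betas", "graph", "group", "behavior")) {
      man <- run_stage(s, cfg)
    }
    return(invisible(man))
  }
  upstream <- c(simulate = NA, betas = "simulate", graph = "betas",
                group = "graph", behavior = "group")[[stage]]
  if (!is.na(upstream) &&
      !file.exists(file.path(cfg$workdir, paste0("manifest_", upstream,
                                                 ".json")))) {
    stop("missing upstream artifacts for stage '", stage,
         "': run stage '", upstream, "' first")
  }
  if (cfg$verbosity > 0) message("[tmrnet] stage ", stage)
  fun <- switch(stage, simulate = stage_simulate, betas = stage_betas,
                graph = stage_graph, group = stage_group,
                behavior = stage_behavior)
  invisible(fun(cfg))
}

wd_path <- function(cfg, ...) file.path(cfg$workdir, ...)
sub_tag <- function(s) sprintf("sub-%02d", s)

write_manifest <- function(cfg, stage, params, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("tmrnet")),
              seed = cfg$seeds[[stage]] %||% cfg$seed,
              params = params,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)))
  path <- wd_path(cfg, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  man
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subject_truth <- function(cfg, pc_effect) {
  args <- utils::modifyList(list(n_parcels = cfg$n_parcels,
                                 seed_cross_boost = pc_effect),
                            cfg$truth)
  args$n_parcels <- cfg$n_parcels
  do.call(network_ground_truth, args)
}

stage_simulate <- function(cfg) {
  seed <- cfg$seeds$simulate
  parc <- generate_parcellation(cfg$grid, cfg$n_parcels, rng_seed = seed)
  write_labels_nifti(parc, wd_path(cfg, "parcellation.nii.gz"))
  set.seed(seed)
  pc_effects <- rtrunc0(cfg$n_subjects, 0.25, 0.1)
  outputs <- wd_path(cfg, "parcellation.nii.gz")
  spec <- do.call(protocol_spec, cfg$protocol)
  for (s in seq_len(cfg$n_subjects)) {
    ev <- generate_protocol(spec, rng_seed = seed + 7L * s)
    truth <- subject_truth(cfg, pc_effects[s])
    sim <- generate_bold(ev, parc, truth, rng_seed = seed + 7L * s + 1L)
    tag <- sub_tag(s)
    write_events(ev, wd_path(cfg, paste0(tag, "_events.tsv")))
    write_bold_nifti(sim$bold, wd_path(cfg, paste0(tag, "_bold.nii.gz")),
                     tr = attr(ev, "tr"))
    utils::write.table(sim$nuisance,
                       wd_path(cfg, paste0(tag, "_nuisance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(attr(ev, "n_scans")),
               wd_path(cfg, paste0(tag, "_nscans.txt")))
    outputs <- c(outputs, wd_path(cfg, paste0(tag, c("_events.tsv",
                                                     "_bold.nii.gz",
                                                     "_nuisance.tsv",
                                                     "_nscans.txt"))))
  }
  beh_args <- utils::modifyList(
    list(n_subjects = cfg$n_subjects, pc_effects = pc_effects,
         rng_seed = seed + 9999L),
    cfg$behavior)
  beh <- do.call(generate_behavior, beh_args)
  utils::write.table(beh, wd_path(cfg, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth0 <- subject_truth(cfg, 0.25)
  jsonlite::write_json(
    list(parcel_module = truth0$parcel_module,
         seed_parcel = truth0$seed_parcel, pc_effects = pc_effects,
         truth_params = cfg$truth),
    wd_path(cfg, "truth.json"), auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, wd_path(cfg, c("behavior.tsv", "truth.json")))
  write_manifest(cfg, "simulate",
                 list(n_subjects = cfg$n_subjects, grid = cfg$grid,
                      n_parcels = cfg$n_parcels, protocol = cfg$protocol,
                      truth = cfg$truth),
                 character(0), outputs)
}

subject_events <- function(cfg, s) {
  tag <- sub_tag(s)
  n_scans <- as.integer(readLines(wd_path(cfg, paste0(tag, "_nscans.txt"))))
  spec <- do.call(protocol_spec, cfg$protocol)
  read_events(wd_path(cfg, paste0(tag, "_events.tsv")), tr = spec$tr,
              n_scans = n_scans)
}

stage_betas <- function(cfg) {
  inputs <- character(0); outputs <- character(0)
  for (s in seq_len(cfg$n_subjects)) {
    tag <- sub_tag(s)
    ev <- subject_events(cfg, s)
    bold <- read_bold_nifti(wd_path(cfg, paste0(tag, "_bold.nii.gz")))
    nuis <- utils::read.delim(wd_path(cfg, paste0(tag, "_nuisance.tsv")))
    des <- build_design(ev, nuisance = nuis, cutoff = cfg$analysis$cutoff)
    bs <- fit_betas(t(bold), des, ar1 = cfg$analysis$ar1)
    bs$grid <- attr(bold, "grid")
    splits <- split_by_condition(bs)
    for (cond in names(splits)) {
      b <- splits[[cond]]$betas
      attr(b, "grid") <- bs$grid
      write_bold_nifti(t(b), wd_path(cfg, paste0(tag, "_betas_", cond,
                                                 ".nii.gz")))
      outputs <- c(outputs, wd_path(cfg, paste0(tag, "_betas_", cond,
                                                ".nii.gz")))
    }
    inputs <- c(inputs, wd_path(cfg, paste0(tag, c("_events.tsv",
                                                   "_bold.nii.gz",
                                                   "_nuisance.tsv"))))
  }
  write_manifest(cfg, "betas",
                 list(cutoff = cfg$analysis$cutoff, ar1 = cfg$analysis$ar1),
                 inputs, outputs)
}

read_subject_betas <- function(cfg, s, cond) {
  tag <- sub_tag(s)
  series <- read_bold_nifti(wd_path(cfg, paste0(tag, "_betas_", cond,
                                                ".nii.gz")))
  out <- list(betas = t(series), trial_type = rep(cond, nrow(series)),
              node_type = "voxel", grid = attr(series, "grid"),
              rho = NULL)
  class(out) <- "beta_series"
  out
}

stage_graph <- function(cfg) {
  parc <- read_labels_nifti(wd_path(cfg, "parcellation.nii.gz"))
  ana <- cfg$analysis
  inputs <- wd_path(cfg, "parcellation.nii.gz"); outputs <- character(0)
  for (s in seq_len(cfg$n_subjects)) {
    tag <- sub_tag(s)
    for (cond in c("cue", "control")) {
      bs <- read_subject_betas(cfg, s, cond)
      inputs <- c(inputs, wd_path(cfg, paste0(tag, "_betas_", cond,
                                              ".nii.gz")))
      coarse <- parcel_average(bs, parc)
      g_coarse <- threshold_fdr(correlation_matrix(coarse), q = ana$q)
      part <- louvain_partition(g_coarse, gamma = ana$gamma,
                                n_restarts = ana$n_restarts,
                                rng_seed = cfg$seeds$graph + s)
      vox_labels <- propagate_modules(part, parc)
      g_fine <- threshold_fdr(
        correlation_matrix(bs, max_nodes = max(2000, prod(cfg$grid))),
        q = ana$q)
      pc <- participation_coefficient(g_fine, vox_labels)
      write_map_nifti(pc, wd_path(cfg, paste0(tag, "_pc_", cond, ".nii.gz")),
                      grid = cfg$grid)
      write_matrix_tsv(g_coarse$W,
                       wd_path(cfg, paste0(tag, "_coarse_", cond, ".tsv")))
      utils::write.table(
        data.frame(parcel = seq_along(part$membership),
                   module = part$membership),
        wd_path(cfg, paste0(tag, "_partition_", cond, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs,
                   wd_path(cfg, paste0(tag, c(paste0("_pc_", cond, ".nii.gz"),
                                              paste0("_coarse_", cond, ".tsv"),
                                              paste0("_partition_", cond,
                                                     ".tsv")))))
    }
  }
  write_manifest(cfg, "graph",
                 list(q = ana$q, gamma = ana$gamma,
                      n_restarts = ana$n_restarts),
                 inputs, outputs)
}

read_pc_maps <- function(cfg) {
  nv <- prod(cfg$grid)
  cue <- matrix(NA_real_, cfg$n_subjects, nv)
  ctl <- matrix(NA_real_, cfg$n_subjects, nv)
  for (s in seq_len(cfg$n_subjects)) {
    cue[s, ] <- as.numeric(read_map_nifti(
      wd_path(cfg, paste0(sub_tag(s), "_pc_cue.nii.gz"))))
    ctl[s, ] <- as.numeric(read_map_nifti(
      wd_path(cfg, paste0(sub_tag(s), "_pc_control.nii.gz"))))
  }
  list(cue = cue, control = ctl)
}

# synthetic ROI masks standing in for anatomical atlas masks:
# unions of parcels outside the planted seed module, two parcels per ROI
roi_masks_from_truth <- function(cfg, parc, n_rois) {
  truth <- jsonlite::read_json(wd_path(cfg, "truth.json"),
                               simplifyVector = TRUE)
  mods <- truth$parcel_module
  seed_mod <- mods[truth$seed_parcel]
  cand <- which(mods != seed_mod)
  masks <- list()
  for (i in seq_len(n_rois)) {
    parcels <- cand[(2 * i - 1):(2 * i)]
    masks[[sprintf("roi_%d", i)]] <- as.integer(parc) %in% parcels
  }
  masks
}

stage_group <- function(cfg) {
  ana <- cfg$analysis
  parc <- read_labels_nifti(wd_path(cfg, "parcellation.nii.gz"))
  pc <- read_pc_maps(cfg)
  pc_map <- paired_t_map(pc$cue, pc$control, grid = cfg$grid,
                         contrast = "participation coefficient: cue - control")
  write_map_nifti(pc_map$z, wd_path(cfg, "group_pc_zmap.nii.gz"),
                  grid = cfg$grid)
  clusters <- cluster_inference(pc_map, z_threshold = ana$z_threshold,
                                method = "permutation", n_perm = ana$n_perm,
                                rng_seed = cfg$seeds$group,
                                connectivity = ana$connectivity)
  utils::write.table(clusters, wd_path(cfg, "group_pc_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # seed region: significant PC cluster if any, else largest cluster,
  # else the planted seed parcel
  truth <- jsonlite::read_json(wd_path(cfg, "truth.json"),
                               simplifyVector = TRUE)
  vox <- attr(clusters, "voxels")
  seed_nodes <- if (nrow(clusters) > 0 && any(clusters$p_corrected < 0.05)) {
    vox[[which.min(clusters$p_corrected)]]
  } else if (nrow(clusters) > 0) {
    vox[[1]]
  } else {
    which(as.integer(parc) == truth$seed_parcel)
  }
  writeLines(as.character(seed_nodes), wd_path(cfg, "seed_nodes.txt"))

  betas <- lapply(seq_len(cfg$n_subjects), function(s)
    list(cue = read_subject_betas(cfg, s, "cue"),
         control = read_subject_betas(cfg, s, "control")))
  seed_map <- seed_contrast_map(seed_nodes, betas, grid = cfg$grid)
  write_map_nifti(ifelse(is.na(seed_map$z), 0, seed_map$z),
                  wd_path(cfg, "group_seed_zmap.nii.gz"), grid = cfg$grid)
  seed_clusters <- cluster_inference(seed_map, z_threshold = ana$z_threshold,
                                     method = "permutation",
                                     n_perm = ana$n_perm,
                                     rng_seed = cfg$seeds$group + 1L,
                                     connectivity = ana$connectivity)
  utils::write.table(seed_clusters, wd_path(cfg, "group_seed_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rois6 <- roi_masks_from_truth(cfg, parc, ana$n_rois_seed %||% 6)
  svc_seed <- small_volume_correct(seed_map, rois6,
                                   z_threshold = ana$z_threshold, q = 0.05,
                                   method = "permutation",
                                   n_perm = ana$n_perm,
                                   rng_seed = cfg$seeds$group + 2L,
                                   connectivity = ana$connectivity)
  utils::write.table(cbind(svc_seed$table, critical_p = svc_seed$critical_p),
                     wd_path(cfg, "group_seed_svc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # covariate analysis: subject seed-connectivity contrasts against the
  # subject's PC increase in the seed region
  pc_inc <- rowMeans(pc$cue[, seed_nodes, drop = FALSE]) -
    rowMeans(pc$control[, seed_nodes, drop = FALSE])
  writeLines(format(pc_inc, digits = 17), wd_path(cfg, "pc_increase.txt"))
  cov_map <- covariate_map(seed_map$subject_contrasts, pc_inc,
                           grid = cfg$grid)
  write_map_nifti(ifelse(is.na(cov_map$z), 0, cov_map$z),
                  wd_path(cfg, "group_covariate_zmap.nii.gz"),
                  grid = cfg$grid)
  rois2 <- roi_masks_from_truth(cfg, parc, ana$n_rois_covariate %||% 2)
  svc_cov <- small_volume_correct(cov_map, rois2,
                                  z_threshold = ana$z_threshold, q = 0.05,
                                  method = "permutation",
                                  n_perm = ana$n_perm,
                                  rng_seed = cfg$seeds$group + 3L,
                                  connectivity = ana$connectivity)
  utils::write.table(cbind(svc_cov$table, critical_p = svc_cov$critical_p),
                     wd_path(cfg, "group_covariate_svc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- wd_path(cfg, c("group_pc_zmap.nii.gz", "group_pc_clusters.tsv",
                            "seed_nodes.txt", "group_seed_zmap.nii.gz",
                            "group_seed_clusters.tsv", "group_seed_svc.tsv",
                            "pc_increase.txt",
                            "group_covariate_zmap.nii.gz",
                            "group_covariate_svc.tsv"))
  write_manifest(cfg, "group",
                 list(z_threshold = ana$z_threshold, n_perm = ana$n_perm,
                      connectivity = ana$connectivity),
                 character(0), outputs)
}

stage_behavior <- function(cfg) {
  beh <- utils::read.delim(wd_path(cfg, "behavior.tsv"))
  beh$cued <- as.logical(beh$cued)
  class(beh) <- c("behavioral_table", "data.frame")
  summ <- forgetting_summary(beh)
  pc_inc <- as.numeric(readLines(wd_path(cfg, "pc_increase.txt")))
  per <- summ$per_subject
  k_all <- kendall_tau(pc_inc, per$delta)
  k_cued <- kendall_tau(pc_inc, per$delta_cued)
  k_uncued <- kendall_tau(pc_inc, per$delta_uncued)
  wh <- williams_hotelling(stats::cor(pc_inc, per$delta_cued),
                           stats::cor(pc_inc, per$delta_uncued),
                           stats::cor(per$delta_cued, per$delta_uncued),
                           n = nrow(per))
  utils::write.table(per, wd_path(cfg, "behavior_per_subject.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(group = summ$group,
         kendall = list(overall = k_all, cued = k_cued, uncued = k_uncued),
         williams_hotelling = wh),
    wd_path(cfg, "behavior_stats.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "behavior", list(),
                 wd_path(cfg, c("behavior.tsv", "pc_increase.txt")),
                 wd_path(cfg, c("behavior_per_subject.tsv",
                                "behavior_stats.json")))
}
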