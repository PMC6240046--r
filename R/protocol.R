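#' Cueing-protocol specification
#'
#' Parameters of the in-scanner sound-presentation protocol during slow-wave
#' sleep. Defaults reproduce the study design: 25 cue sounds presented twice
#' (50 cue trials) and 5 control sounds presented five times (25 control
#' trials), grouped in blocks of five 500 ms presentations separated by a
#' 4-8 s jittered inter-stimulus interval; each presentation is modelled
#' downstream as a 5 s boxcar to absorb uncertainty about the onset and
#' duration of the induced reactivation.
#'
#' @param n_cue_sounds Number of distinct cue sounds.
#' @param cue_repetitions Presentations per cue sound.
#' @param n_control_sounds Number of distinct control sounds.
#' @param control_repetitions Presentations per control sound.
#' @param sound_duration Physical sound duration (seconds).
#' @param model_duration Boxcar duration used in the GLM (seconds).
#' @param isi_range Length-2 numeric, uniform jitter bounds for the
#'   inter-stimulus interval (seconds), measured from sound offset to the
#'   next onset.
#' @param block_size Presentations per block (blocks are
#'   condition-homogeneous).
#' @param tr Repetition time of the accompanying acquisition (seconds).
#' @param n_scans Number of scans; `NULL` sizes the run automatically to the
#'   generated events plus a 30 s tail.
#' @param start_time Onset of the first presentation (seconds).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_cue_sounds = 25, cue_repetitions = 2,
                          n_control_sounds = 5, control_repetitions = 5,
                          sound_duration = 0.5, model_duration = 5,
                          isi_range = c(4, 8), block_size = 5,
                          tr = 2.511, n_scans = NULL, start_time = 10) {
  stopifnot(length(isi_range) == 2, isi_range[1] <= isi_range[2],
            isi_range[1] >= 0, sound_duration > 0, model_duration > 0,
            tr > 0, block_size >= 1, start_time >= 0)
  if (n_cue_sounds < 0 || cue_repetitions < 0 ||
      n_control_sounds < 0 || control_repetitions < 0) {
    stop("sound counts and repetitions must be non-negative")
  }
  spec <- list(n_cue_sounds = n_cue_sounds, cue_repetitions = cue_repetitions,
               n_control_sounds = n_control_sounds,
               control_repetitions = control_repetitions,
               sound_duration = sound_duration, model_duration = model_duration,
               isi_range = as.numeric(isi_range), block_size = block_size,
               tr = tr, n_scans = n_scans, start_time = start_time)
  class(spec) <- "protocol_spec"
  spec
}

#' Generate a randomized trial sequence for the cueing protocol
#'
#' Presentations of each condition are shuffled and chunked into
#' condition-homogeneous blocks of `block_size`; block order is then
#' randomized. Each presentation is followed by an ISI drawn uniformly from
#' `isi_range` (the ISI after a block's last presentation separates blocks).
#'
#' @param spec A [protocol_spec()].
#' @param rng_seed Integer seed; the sequence is deterministic given the
#'   seed.
#' @return A `data.frame` (class `trial_events`) with columns `onset`,
#'   `duration` (the GLM model duration), `trial_type` (`"cue"` or
#'   `"control"`), `sound_id`, `block_index`, and attributes `tr`,
#'   `n_scans`, `sound_duration`.
#' @export
generate_protocol <- function(spec = protocol_spec(), rng_seed = 1) {
  stopifnot(inherits(spec, "protocol_spec"))
  n_cue <- spec$n_cue_sounds * spec$cue_repetitions
  n_ctl <- spec$n_control_sounds * spec$control_repetitions
  if (n_cue == 0 && n_ctl == 0) stop("both conditions have zero presentations")
  if (n_cue == 0) warning("cue condition absent (zero presentations)")
  if (n_ctl == 0) warning("control condition absent (zero presentations)")
  if (n_cue %% spec$block_size != 0 || n_ctl %% spec$block_size != 0) {
    stop("presentation counts must be multiples of block_size for ",
         "condition-homogeneous blocks")
  }
  set.seed(as.integer(rng_seed))
  cue_ids <- if (n_cue > 0) {
    sample(rep(paste0("cue_", seq_len(spec$n_cue_sounds)),
               spec$cue_repetitions))
  } else character(0)
  ctl_ids <- if (n_ctl > 0) {
    sample(rep(paste0("control_", seq_len(spec$n_control_sounds)),
               spec$control_repetitions))
  } else character(0)
  blocks <- c(
    if (n_cue > 0) lapply(split(cue_ids, ceiling(seq_along(cue_ids) /
                                                   spec$block_size)),
                          function(ids) list(type = "cue", ids = ids)),
    if (n_ctl > 0) lapply(split(ctl_ids, ceiling(seq_along(ctl_ids) /
                                                   spec$block_size)),
                          function(ids) list(type = "control", ids = ids))
  )
  blocks <- blocks[sample(length(blocks))]

  n_trials <- n_cue + n_ctl
  isi <- stats::runif(n_trials, spec$isi_range[1], spec$isi_range[2])
  onset <- numeric(n_trials); trial_type <- character(n_trials)
  sound_id <- character(n_trials); block_index <- integer(n_trials)
  t_cur <- spec$start_time; k <- 0L
  for (b in seq_along(blocks)) {
    for (id in blocks[[b]]$ids) {
      k <- k + 1L
      onset[k] <- t_cur
      trial_type[k] <- blocks[[b]]$type
      sound_id[k] <- id
      block_index[k] <- b
      t_cur <- t_cur + spec$sound_duration + isi[k]
    }
  }
  events <- data.frame(onset = onset, duration = spec$model_duration,
                       trial_type = trial_type, sound_id = sound_id,
                       block_index = block_index,
                       stringsAsFactors = FALSE)
  run_end <- max(events$onset + events$duration)
  n_scans_min <- ceiling((run_end + 30) / spec$tr)
  if (is.null(spec$n_scans)) {
    n_scans <- n_scans_min
  } else {
    n_scans <- spec$n_scans
    if (n_scans * spec$tr < run_end) {
      stop(sprintf("run too short: need at least %d scans of TR %.3f s to hold all events",
                   ceiling(run_end / spec$tr), spec$tr))
    }
  }
  attr(events, "tr") <- spec$tr
  attr(events, "n_scans") <- as.integer(n_scans)
  attr(events, "sound_duration") <- spec$sound_duration
  class(events) <- c("trial_events", "data.frame")
  events
}

#' Write / read trial events as BIDS-style TSV
#'
#' @param events A `trial_events` data frame.
#' @param path Output TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `trial_events` data frame (attributes `tr`/`n_scans` must be supplied).
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr,n_scans Acquisition timing to attach to the read events.
#' @export
read_events <- function(path, tr, n_scans) {
  events <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  if (!all(req %in% names(events))) {
    stop("events TSV must contain columns: ", paste(req, collapse = ", "))
  }
  attr(events, "tr") <- tr
  attr(events, "n_scans") <- as.integer(n_scans)
  class(events) <- c("trial_events", "data.frame")
  events
}
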