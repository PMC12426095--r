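# File dialects: motion, gaze and design CSVs, and the pipeline config block.
# All CSVs are UTF-8, comma-delimited, with a mandatory header row; times are
# seconds as decimals. Arm motion is written on the vertical (z) axis and
# head motion on the anterior-posterior (x) axis; unused axes are zero.

axis_column <- c(vertical = "z", anterior_posterior = "x", lateral = "y")

#' Write dyad-trial motion channels to the standard motion CSV
#'
#' Columns: `participant_id, trial_id, actor, channel, t_s, x, y, z`.
#'
#' @param trials named list of `dyad_trial`s (keyed by trial id).
#' @param path output file path.
#' @param stage optional stage marker column value (e.g. `"preprocessed"`).
#' @return the path, invisibly.
#' @export
write_motion_csv <- function(trials, path, stage = NULL) {
  rows <- list()
  for (tid in names(trials)) {
    tr <- trials[[tid]]
    for (nm in names(tr)) {
      mt <- tr[[nm]]
      if (!inherits(mt, "movement_trial")) next
      n <- length(mt$samples)
      df <- data.frame(
        participant_id = mt$meta$participant_id %||% NA_character_,
        trial_id = tid, actor = mt$actor, channel = mt$channel,
        t_s = (seq_len(n) - 1) / mt$rate, x = 0, y = 0, z = 0,
        stringsAsFactors = FALSE)
      df[[axis_column[[mt$axis]]]] <- mt$samples
      if (!is.null(stage)) df$stage <- stage
      rows[[paste(tid, nm)]] <- df
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read the standard motion CSV back into dyad trials
#'
#' Inverse of [write_motion_csv()]: arm channels are read from the vertical
#' axis and head channels from the anterior-posterior axis.
#'
#' @param path motion CSV path.
#' @return named list of `dyad_trial`s keyed by trial id.
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_id", "actor", "channel", "t_s",
            "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_invalid("motion CSV lacks required columns")
  }
  trials <- list()
  for (tid in unique(df$trial_id)) {
    sub <- df[df$trial_id == tid, ]
    tr <- list(meta = list(participant_id = sub$participant_id[1],
                           trial_id = tid))
    for (actor in unique(sub$actor)) {
      for (channel in unique(sub$channel[sub$actor == actor])) {
        s <- sub[sub$actor == actor & sub$channel == channel, ]
        s <- s[order(s$t_s), ]
        if (nrow(s) < 2) stop_insufficient("trial ", tid, " has < 2 samples")
        dt <- diff(s$t_s)
        if (max(abs(dt - dt[1])) > 1e-6) {
          stop_invalid("non-uniform sampling in trial ", tid)
        }
        axis <- if (channel == "arm") "vertical" else "anterior_posterior"
        x <- s[[axis_column[[axis]]]]
        if (anyNA(x)) stop_invalid("missing samples in trial ", tid)
        tr[[paste(actor, channel, sep = "_")]] <-
          movement_trial(x, 1 / dt[1], actor, channel, axis, tr$meta)
        tr$rate <- 1 / dt[1]
      }
    }
    tr$duration <- length(tr[[2]]$samples) / tr$rate
    trials[[tid]] <- structure(tr, class = "dyad_trial")
  }
  trials
}

#' Write gaze streams to the standard gaze CSV
#'
#' Columns: `participant_id, trial_id, t_s, aoi`.
#'
#' @param gaze named list of `gaze_stream`s keyed by trial id.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gaze_csv <- function(gaze, path) {
  rows <- lapply(names(gaze), function(tid) {
    gs <- gaze[[tid]]
    data.frame(
      participant_id = gs$meta$participant_id %||% NA_character_,
      trial_id = tid, t_s = (seq_along(gs$labels) - 1) / gs$rate,
      aoi = gs$labels, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read the standard gaze CSV
#'
#' @param path gaze CSV path.
#' @return named list of `gaze_stream`s keyed by trial id.
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "trial_id", "t_s", "aoi") %in% names(df))) {
    stop_invalid("gaze CSV lacks required columns")
  }
  out <- list()
  for (tid in unique(df$trial_id)) {
    s <- df[df$trial_id == tid, ]
    s <- s[order(s$t_s), ]
    dt <- diff(s$t_s)
    rate <- 1 / dt[1]
    out[[tid]] <- structure(
      list(labels = s$aoi, rate = rate, duration = nrow(s) / rate,
           meta = list(participant_id = s$participant_id[1], trial_id = tid)),
      class = "gaze_stream")
  }
  out
}

#' Write the trial-design CSV
#'
#' Columns: `participant_id, gaze_condition, trial_id, focus_condition,
#' trial_order`.
#'
#' @param design_table design table from [generate_experiment()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_design_csv <- function(design_table, path) {
  utils::write.csv(
    design_table[, c("participant_id", "gaze_condition", "trial_id",
                     "focus_condition", "trial_order")],
    path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run; serialises losslessly to and
#' from YAML via [write_config()] / [read_config()].
#'
#' @param n_per_group participants per avatar-gaze group.
#' @param sampling_rate samples per second (default 50).
#' @param trial_duration trial length in seconds (default 45).
#' @param discard,keep trimming window in seconds (defaults 5 and 40).
#' @param cutoff Butterworth low-pass cutoff in Hz (default 10).
#' @param phase_mode rho convention, `"doubled"` or `"resultant"`.
#' @param crqa_delay,crqa_dimension embedding parameters; `NA` means estimate
#'   from the avatar head series (pooled across trials).
#' @param crqa_radius recurrence radius in signal units (default 12).
#' @param seed master integer seed.
#' @param arm_coupling,head_coupling per-cell coupling maps (see
#'   [experiment_design()]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 20, sampling_rate = 50,
                            trial_duration = 45, discard = 5, keep = 40,
                            cutoff = 10, phase_mode = "doubled",
                            crqa_delay = NA, crqa_dimension = NA,
                            crqa_radius = 12, seed = 1L,
                            arm_coupling = NULL, head_coupling = NULL) {
  cfg <- list(n_per_group = n_per_group, sampling_rate = sampling_rate,
              trial_duration = trial_duration, discard = discard, keep = keep,
              cutoff = cutoff, phase_mode = phase_mode,
              crqa_delay = crqa_delay, crqa_dimension = crqa_dimension,
              crqa_radius = crqa_radius, seed = as.integer(seed),
              arm_coupling = arm_coupling, head_coupling = head_coupling)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}
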