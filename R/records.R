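# Assembly of the per-trial analysis table and a record-level simulator used
# for calibrating the inference stage.

#' Assemble the per-trial analysis table from pipeline outputs
#'
#' One row per trial: ids, numeric condition codes (focus 1 = self,
#' 2 = other; gaze 1 = direct, 2 = averted), coordination outcomes and AOI
#' dwell percentages.
#'
#' @param design_table the design table from [generate_experiment()].
#' @param phase_results named list of `phase_result`s keyed by trial id.
#' @param crqa_results named list of `crqa_result`s keyed by trial id.
#' @param gaze_summaries named list of `gaze_summary`s keyed by trial id.
#' @return a `data.frame` of trial records.
#' @export
trial_records <- function(design_table, phase_results, crqa_results,
                          gaze_summaries) {
  ids <- design_table$trial_id
  data.frame(
    participant_id = design_table$participant_id,
    trial_id = ids,
    focus = ifelse(design_table$focus_condition == "self", 1, 2),
    gaze = ifelse(design_table$gaze_condition == "direct", 1, 2),
    trial_order = design_table$trial_order,
    rho = vapply(ids, function(i) phase_results[[i]]$rho, numeric(1)),
    rho_fisher = vapply(ids, function(i) phase_results[[i]]$rho_fisher,
                        numeric(1)),
    percent_recurrence = vapply(ids, function(i)
      crqa_results[[i]]$percent_recurrence, numeric(1)),
    pct_avatar = vapply(ids, function(i) gaze_summaries[[i]]$pct_avatar,
                        numeric(1)),
    pct_near = vapply(ids, function(i) gaze_summaries[[i]]$pct_near,
                      numeric(1)),
    pct_room = vapply(ids, function(i) gaze_summaries[[i]]$pct_room,
                      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate trial records directly at the outcome level
#'
#' Generates the per-trial analysis table from a known linear model —
#' outcome = b0 + b_focus * focus + b_gaze * gaze + b_fg * focus * gaze
#' (+ optionally an AOI-by-focus interaction) + participant intercept +
#' residual — bypassing the signal stages. Used to calibrate type-I error and
#' effect recovery of the model stage against known truth.
#'
#' @param n_per_group participants per gaze group.
#' @param effects named list of true fixed effects on the 1/2 coding scale:
#'   `intercept`, `focus`, `gaze`, `interaction` (defaults all 0).
#' @param sd_participant SD of the by-participant random intercept.
#' @param sd_residual residual SD.
#' @param aoi_sd SD of the simulated (centred) AOI percentage columns.
#' @param aoi_focus_effect slope of the `pct_avatar x focus` interaction on
#'   the outcome (0 = AOI columns are pure noise).
#' @param seed integer seed.
#' @return a `data.frame` with columns `participant_id`, `focus`, `gaze`,
#'   `outcome`, `pct_avatar`, `pct_near`, `pct_room`.
#' @export
simulate_trial_records <- function(n_per_group = 20,
                                   effects = list(),
                                   sd_participant = 0.3,
                                   sd_residual = 0.5,
                                   aoi_sd = 10,
                                   aoi_focus_effect = 0,
                                   seed = 1L) {
  eff <- utils::modifyList(
    list(intercept = 0, focus = 0, gaze = 0, interaction = 0), effects)
  n_pp <- 2L * n_per_group
  with_seed(seed, {
    pid <- rep(sprintf("P%03d", seq_len(n_pp)), each = 2)
    gaze <- rep(rep(c(1, 2), each = n_per_group), each = 2)
    focus <- rep(c(1, 2), times = n_pp)
    u <- rep(stats::rnorm(n_pp, sd = sd_participant), each = 2)
    pa <- stats::rnorm(2 * n_pp, sd = aoi_sd)
    pn <- stats::rnorm(2 * n_pp, sd = aoi_sd)
    pr <- stats::rnorm(2 * n_pp, sd = aoi_sd)
    y <- eff$intercept + eff$focus * focus + eff$gaze * gaze +
      eff$interaction * focus * gaze +
      aoi_focus_effect * (pa - mean(pa)) * (focus - 1.5) +
      u + stats::rnorm(2 * n_pp, sd = sd_residual)
    data.frame(participant_id = pid, focus = focus, gaze = gaze,
               outcome = y, pct_avatar = pa, pct_near = pn, pct_room = pr,
               stringsAsFactors = FALSE)
  })
}
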