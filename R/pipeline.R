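# End-to-end orchestration of the synthetic experiment and analysis.

#' Run the full coordination pipeline on a synthetic experiment
#'
#' Sequences the stages in analysis order: generate the 2x2 experiment,
#' preprocess every channel (trim, standardise, centre, zero-phase filter),
#' estimate arm coordination (Hilbert relative phase, rho, Fisher transform),
#' estimate head coordination (%REC at the configured or avatar-estimated
#' embedding), summarise gaze dwell times over the same analysis window,
#' assemble the per-trial table, and fit the mixed models for both outcomes
#' including the AOI model-fit comparisons.
#'
#' Deterministic given `config$seed`. If `out_dir` is given, writes
#' `trials.csv` (per-trial table), `design.csv`, `motion_raw.csv`,
#' `gaze.csv` and `report.json` there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @param write_motion write the (large) raw motion CSV too (default FALSE).
#' @return list with `records` (per-trial table), `embedding` (delay,
#'   dimension and flags), `models` (per outcome: the `model_fit`, AOI
#'   comparisons, post hoc contrasts when the interaction is informative),
#'   and `provenance` (seed, config, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_motion = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  design_args <- list(
    n_per_group = config$n_per_group, trial_duration = config$trial_duration,
    sampling_rate = config$sampling_rate, seed = config$seed)
  if (!is.null(config$arm_coupling)) {
    design_args$arm_coupling <- unlist(config$arm_coupling)
  }
  if (!is.null(config$head_coupling)) {
    design_args$head_coupling <- unlist(config$head_coupling)
  }
  design <- do.call(experiment_design, design_args)
  exper <- generate_experiment(design)

  pre <- lapply(exper$trials, preprocess_dyad, discard = config$discard,
                keep = config$keep, cutoff = config$cutoff)

  phase_results <- lapply(pre, phase_coordination, mode = config$phase_mode)

  delay <- config$crqa_delay
  dimension <- config$crqa_dimension
  embedding <- list(delay = delay, dimension = dimension, estimated = FALSE)
  if (is.na(delay) || is.na(dimension)) {
    # pooled estimation across trials from the avatar (reference) series
    est <- estimate_embedding(lapply(pre, function(tr) tr$avatar_head),
                              rate = config$sampling_rate)
    if (is.na(delay)) delay <- est$delay
    if (is.na(dimension)) dimension <- est$dimension
    embedding <- list(delay = delay, dimension = dimension, estimated = TRUE,
                      delay_no_minimum = est$delay_no_minimum,
                      dimension_no_minimum = est$dimension_no_minimum)
  }
  crqa_results <- lapply(pre, crqa_trial, delay = delay,
                         dimension = dimension, radius = config$crqa_radius)

  gaze_summaries <- lapply(exper$gaze, function(gs)
    summarize_gaze(trim_gaze(gs, config$discard, config$keep)))

  records <- trial_records(exper$design_table, phase_results, crqa_results,
                           gaze_summaries)

  models <- list()
  for (outcome in c("rho_fisher", "percent_recurrence")) {
    fit <- fit_coordination_model(records, outcome, transform = "auto")
    comparisons <- lapply(c("pct_avatar", "pct_near", "pct_room"),
                          function(a) compare_models_aoi(records, outcome, a))
    names(comparisons) <- c("pct_avatar", "pct_near", "pct_room")
    posthoc <- tryCatch(posthoc_contrasts(fit, by = "focus"),
                        error = function(e) NULL)
    models[[outcome]] <- list(fit = fit, aoi_comparisons = comparisons,
                              posthoc_gaze_by_focus = posthoc)
  }

  result <- list(
    records = records,
    embedding = embedding,
    models = models,
    provenance = list(
      seed = config$seed,
      config = unclass(config),
      package_version = as.character(utils::packageVersion("dyadsync"))
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    write_design_csv(exper$design_table, file.path(out_dir, "design.csv"))
    write_gaze_csv(exper$gaze, file.path(out_dir, "gaze.csv"))
    if (write_motion) {
      write_motion_csv(exper$trials, file.path(out_dir, "motion_raw.csv"))
    }
    report <- list(
      provenance = result$provenance,
      embedding = embedding,
      models = lapply(models, function(m) list(
        coefficients = m$fit$coefficients,
        transformed = m$fit$transformed,
        df_method = m$fit$df_method,
        converged = m$fit$converged,
        aoi_comparisons = lapply(m$aoi_comparisons, function(cp)
          cp[c("chisq", "df", "p", "converged", "aoi")])
      ))
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
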