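# Inference stage: linear mixed-effects models with a by-participant random
# intercept, Satterthwaite degrees of freedom, a residual-normality gate with
# log-transform fallback, likelihood-ratio AOI model comparisons, and
# Tukey-corrected post hoc contrasts.

# a singular (boundary) fit is flagged separately, not a convergence failure
fit_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  length(msgs[!grepl("boundary \\(singular\\)", msgs)]) == 0
}

check_records <- function(records, outcome) {
  needed <- c("participant_id", "focus", "gaze", outcome)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_invalid("records lack columns: ", paste(missing, collapse = ", "))
  }
  if (length(unique(records$participant_id)) < 10) {
    stop_insufficient("at least 10 participants are required")
  }
  if (length(unique(records$gaze)) < 2) {
    stop_insufficient("both avatar-gaze groups must be present")
  }
  invisible(TRUE)
}

apply_offset <- function(y) {
  if (all(y > 0)) return(list(y = y, offset = 0))
  pos <- y[y > 0]
  if (!length(pos)) stop_invalid("outcome has no positive values to anchor the log offset")
  offset <- 0.5 * min(pos) - min(y)
  list(y = y + offset, offset = offset)
}

#' Residual-normality gate with log-transform fallback
#'
#' Fits the base mixed model on the raw outcome, applies a Shapiro-Wilk test
#' to the conditional residuals at alpha = .05, and log-transforms the
#' outcome (natural log) when normality is rejected. Non-positive outcomes
#' receive an offset anchored at half the smallest positive observed value,
#' recorded in the result.
#'
#' @param records per-trial data frame (see [trial_records()]).
#' @param outcome name of the outcome column.
#' @param alpha rejection level of the Shapiro-Wilk gate (default 0.05).
#' @return list with `records` (a `.model_outcome` column added on the
#'   analysis scale), `transformed` (logical), `shapiro_p`, `offset`.
#' @export
maybe_log_transform <- function(records, outcome, alpha = 0.05) {
  check_records(records, outcome)
  records$.model_outcome <- records[[outcome]]
  base <- lme4::lmer(.model_outcome ~ focus * gaze + (1 | participant_id),
                     data = records, REML = TRUE)
  sw <- stats::shapiro.test(stats::residuals(base))
  transformed <- sw$p.value < alpha
  offset <- 0
  if (transformed) {
    shifted <- apply_offset(records[[outcome]])
    offset <- shifted$offset
    records$.model_outcome <- log(shifted$y)
  }
  list(records = records, transformed = transformed,
       shapiro_p = sw$p.value, offset = offset)
}

#' Fit the 2x2 coordination mixed model
#'
#' Fits `outcome ~ focus * gaze + (1 | participant_id)` by REML with the
#' study's numeric coding (focus 1 = self, 2 = other; gaze 1 = direct,
#' 2 = averted). Degrees of freedom and p-values use the Satterthwaite
#' approximation. With `transform = "auto"` the outcome is log-transformed
#' when a Shapiro-Wilk test rejects residual normality (see
#' [maybe_log_transform()]).
#'
#' @param records per-trial data frame.
#' @param outcome outcome column name (`"rho_fisher"` or
#'   `"percent_recurrence"`).
#' @param transform `"auto"` (normality-gated), `"none"`, or `"log"`.
#' @return an object of class `model_fit`: list with `model` (the
#'   `lmerModLmerTest` fit), `coefficients` (data frame: term, b, se, df, t,
#'   p), `outcome`, `transformed`, `shapiro_p`, `offset`, `converged`,
#'   `singular`, `df_method = "satterthwaite"`, and `data`.
#' @export
fit_coordination_model <- function(records, outcome,
                                   transform = c("auto", "none", "log")) {
  transform <- match.arg(transform)
  check_records(records, outcome)
  transformed <- FALSE
  shapiro_p <- NA_real_
  offset <- 0
  if (transform == "auto") {
    gate <- maybe_log_transform(records, outcome)
    records <- gate$records
    transformed <- gate$transformed
    shapiro_p <- gate$shapiro_p
    offset <- gate$offset
  } else if (transform == "log") {
    shifted <- apply_offset(records[[outcome]])
    offset <- shifted$offset
    records$.model_outcome <- log(shifted$y)
    transformed <- TRUE
  } else {
    records$.model_outcome <- records[[outcome]]
  }
  fit <- lmerTest::lmer(.model_outcome ~ focus * gaze + (1 | participant_id),
                        data = records, REML = TRUE)
  ct <- stats::coef(summary(fit))
  coefficients <- data.frame(
    term = rownames(ct), b = ct[, "Estimate"], se = ct[, "Std. Error"],
    df = ct[, "df"], t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(model = fit, coefficients = coefficients, outcome = outcome,
         transformed = transformed, shapiro_p = shapiro_p, offset = offset,
         converged = fit_converged(fit),
         singular = lme4::isSingular(fit),
         df_method = "satterthwaite", data = records),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ focus * gaze + (1 | participant)%s\n",
              x$outcome, if (x$transformed) " [log-transformed]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio comparison after adding one AOI predictor
#'
#' Adds one centred AOI dwell-time percentage, its two-way interactions with
#' focus and gaze, and the three-way interaction (four added parameters) to
#' the base `focus * gaze` model, and compares the two by a likelihood-ratio
#' test on maximum-likelihood (not REML) fits.
#'
#' @param records per-trial data frame.
#' @param outcome outcome column name.
#' @param aoi one of `"pct_avatar"`, `"pct_near"`, `"pct_room"`.
#' @param transform outcome transform, as in [fit_coordination_model()] but
#'   defaulting to `"none"`.
#' @param coef_table also refit the augmented model by REML and report its
#'   Satterthwaite coefficient table (default TRUE; disable in simulation
#'   loops that only need the LR statistic).
#' @return list with `chisq`, `df`, `p`, `converged`, `aoi`, and (when
#'   `coef_table`) the augmented fit's coefficient table (`coefficients`)
#'   and `model`.
#' @export
compare_models_aoi <- function(records, outcome,
                               aoi = c("pct_avatar", "pct_near", "pct_room"),
                               transform = c("none", "auto", "log"),
                               coef_table = TRUE) {
  aoi <- match.arg(aoi)
  transform <- match.arg(transform)
  check_records(records, outcome)
  if (!aoi %in% names(records)) stop_invalid("records lack column ", aoi)
  if (transform == "none") {
    records$.model_outcome <- records[[outcome]]
  } else {
    gate <- fit_coordination_model(records, outcome, transform)
    records <- gate$data
  }
  records$.aoi_c <- records[[aoi]] - mean(records[[aoi]])
  base <- lme4::lmer(.model_outcome ~ focus * gaze + (1 | participant_id),
                     data = records, REML = FALSE)
  aug <- lme4::lmer(
    .model_outcome ~ focus * gaze * .aoi_c + (1 | participant_id),
    data = records, REML = FALSE)
  aug_ok <- fit_converged(aug)
  if (!aug_ok) {
    return(list(chisq = NA_real_, df = NA_integer_, p = NA_real_,
                converged = FALSE, aoi = aoi, coefficients = NULL))
  }
  lr <- stats::anova(base, aug)
  out <- list(chisq = lr$Chisq[2], df = lr$Df[2], p = lr$`Pr(>Chisq)`[2],
              converged = TRUE, aoi = aoi)
  if (coef_table) {
    aug_t <- lmerTest::lmer(
      .model_outcome ~ focus * gaze * .aoi_c + (1 | participant_id),
      data = records, REML = TRUE)
    ct <- stats::coef(summary(aug_t))
    out$coefficients <- data.frame(
      term = rownames(ct), b = ct[, "Estimate"], se = ct[, "Std. Error"],
      df = ct[, "df"], t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE)
    out$model <- aug_t
  }
  out
}

#' Tukey-corrected simple-effect contrasts
#'
#' Decomposes the focus-by-gaze interaction into simple effects of one factor
#' at each level of the other, with the family of contrasts adjusted jointly
#' (Tukey-style multivariate-t adjustment via emmeans).
#'
#' @param fit a `model_fit` from [fit_coordination_model()].
#' @param by the conditioning factor, `"focus"` or `"gaze"`; the contrast is
#'   the simple effect of the other factor at each of its levels.
#' @return data frame with columns `by`, `by_level`, `contrast`, `estimate`,
#'   `se`, `df`, `t`, `p_adj`.
#' @export
posthoc_contrasts <- function(fit, by = c("focus", "gaze")) {
  stopifnot(inherits(fit, "model_fit"))
  by <- match.arg(by)
  other <- setdiff(c("focus", "gaze"), by)
  terms <- fit$coefficients$term
  if (!any(grepl(":", terms, fixed = TRUE))) {
    stop_invalid("model contains no interaction term to decompose")
  }
  dat <- fit$data
  if (length(unique(dat[[by]])) < 2 || length(unique(dat[[other]])) < 2) {
    stop_invalid("both factors must have two levels in the data")
  }
  emm <- emmeans::emmeans(
    fit$model, specs = stats::as.formula(paste0("~ ", other, " | ", by)),
    at = list(focus = c(1, 2), gaze = c(1, 2)),
    lmer.df = "satterthwaite")
  cs <- emmeans::contrast(emm, method = "revpairwise")
  sm <- summary(rbind(cs), adjust = "mvt")
  data.frame(
    by = by,
    by_level = sm[[by]],
    contrast = as.character(sm$contrast),
    estimate = sm$estimate, se = sm$SE, df = sm$df, t = sm$t.ratio,
    p_adj = sm$p.value, stringsAsFactors = FALSE
  )
}

#' Simple slopes of an AOI predictor by focus instruction
#'
#' For an augmented AOI model (see [compare_models_aoi()]), estimates the
#' slope of the centred AOI percentage at each focus level and their
#' difference, Tukey/multivariate-t adjusted.
#'
#' @param comparison the result of [compare_models_aoi()] (must have
#'   converged).
#' @param gaze_at the gaze code at which slopes are evaluated (default 1.5,
#'   i.e. averaged over groups).
#' @return data frame of slopes per focus level plus the slope contrast.
#' @export
aoi_trends <- function(comparison, gaze_at = 1.5) {
  if (is.null(comparison$model)) stop_invalid("comparison did not converge")
  tr <- emmeans::emtrends(comparison$model, ~ focus, var = ".aoi_c",
                          at = list(focus = c(1, 2), gaze = gaze_at),
                          lmer.df = "satterthwaite")
  sl <- summary(tr)
  ct <- summary(emmeans::contrast(tr, "revpairwise"), adjust = "mvt")
  rbind(
    data.frame(what = sprintf("slope_focus%d", sl$focus),
               estimate = sl$.aoi_c.trend, se = sl$SE, df = sl$df,
               stringsAsFactors = FALSE),
    data.frame(what = "slope_contrast", estimate = ct$estimate, se = ct$SE,
               df = ct$df, stringsAsFactors = FALSE)
  )
}
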