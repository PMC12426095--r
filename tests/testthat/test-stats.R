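test_that("record assembly codes conditions numerically and keeps pairing", {
  ex <- generate_experiment(experiment_design(n_per_group = 2, seed = 2))
  pre <- lapply(ex$trials, preprocess_dyad)
  ph <- lapply(pre, phase_coordination)
  cr <- lapply(pre, crqa_trial, delay = 20, dimension = 5, radius = 12)
  gz <- lapply(ex$gaze, function(g) summarize_gaze(trim_gaze(g)))
  rec <- trial_records(ex$design_table, ph, cr, gz)
  expect_equal(nrow(rec), 8)
  expect_setequal(rec$focus, c(1, 2))
  expect_setequal(rec$gaze, c(1, 2))
  expect_true(all(table(rec$participant_id) == 2))
  by_p <- tapply(rec$gaze, rec$participant_id, function(g)
    length(unique(g)))
  expect_true(all(by_p == 1))
  expect_true(all(abs(rec$pct_avatar + rec$pct_near + rec$pct_room - 100) <
                    1e-9))
})

test_that("the mixed model recovers a noiseless effect exactly", {
  rec <- simulate_trial_records(n_per_group = 10,
                                effects = list(intercept = 1, gaze = 2.5),
                                sd_participant = 0, sd_residual = 0, seed = 1)
  fit <- suppressWarnings(suppressMessages(
    fit_coordination_model(rec, "outcome", transform = "none")))
  b <- fit$coefficients$b
  names(b) <- fit$coefficients$term
  expect_equal(unname(b["gaze"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(b["(Intercept)"]), 1, tolerance = 1e-9)
  expect_lt(max(abs(b[c("focus", "focus:gaze")])), 1e-9)
})

test_that("with zero random-intercept variance the fit agrees with OLS", {
  rec <- simulate_trial_records(n_per_group = 15, sd_participant = 0,
                                sd_residual = 1, seed = 3)
  fit <- suppressMessages(
    fit_coordination_model(rec, "outcome", transform = "none"))
  expect_true(fit$singular)
  ols <- lm(outcome ~ focus * gaze, data = rec)
  expect_equal(fit$coefficients$b, unname(coef(ols)), tolerance = 1e-6)
})

test_that("recoding focus from (1,2) to (0,1) moves the intercept, not the slope t", {
  rec <- simulate_trial_records(n_per_group = 15,
                                effects = list(focus = 1, intercept = 2),
                                seed = 4)
  f12 <- fit_coordination_model(rec, "outcome", transform = "none")
  rec01 <- rec
  rec01$focus <- rec$focus - 1
  f01 <- fit_coordination_model(rec01, "outcome", transform = "none")
  t12 <- f12$coefficients$t[f12$coefficients$term == "focus"]
  t01 <- f01$coefficients$t[f01$coefficients$term == "focus"]
  expect_equal(t12, t01, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f12$coefficients$b[1], f01$coefficients$b[1])))
})

test_that("model preconditions are enforced", {
  rec <- simulate_trial_records(n_per_group = 15, seed = 5)
  expect_error(fit_coordination_model(rec[rec$gaze == 1, ], "outcome"),
               "insufficient-data")
  expect_error(fit_coordination_model(rec[1:8, ], "outcome"),
               "insufficient-data")
  expect_error(fit_coordination_model(rec, "nope"), "invalid-argument")
})

test_that("the normality gate transforms skewed outcomes and spares Gaussian ones", {
  gauss_hits <- 0L
  log_hits <- 0L
  for (r in 1:40) {
    rec <- simulate_trial_records(n_per_group = 40, sd_participant = 0.2,
                                  sd_residual = 1, seed = 600 + r)
    g <- suppressMessages(maybe_log_transform(rec, "outcome"))
    gauss_hits <- gauss_hits + !g$transformed
    rec$outcome <- exp(rec$outcome)  # strongly log-normal
    l <- suppressMessages(maybe_log_transform(rec, "outcome"))
    log_hits <- log_hits + l$transformed
  }
  expect_gte(gauss_hits, 36)   # no transform in >= 90% of Gaussian runs
  expect_gte(log_hits, 36)     # transform in >= 90% of log-normal runs
})

test_that("forced log transform offsets non-positive outcomes and flags it", {
  rec <- simulate_trial_records(n_per_group = 15, seed = 7,
                                effects = list(intercept = 5))
  fit <- suppressMessages(
    fit_coordination_model(rec, "outcome", transform = "log"))
  expect_true(fit$transformed)
  expect_equal(fit$offset, 0)   # all outcomes already positive
  rec$outcome <- rec$outcome - min(rec$outcome)   # creates an exact zero
  fit2 <- suppressMessages(
    fit_coordination_model(rec, "outcome", transform = "log"))
  expect_gt(fit2$offset, 0)
  expect_true(all(is.finite(fit2$data$.model_outcome)))
})

test_that("the AOI likelihood-ratio comparison adds four parameters", {
  rec <- simulate_trial_records(n_per_group = 20, seed = 8)
  for (aoi in c("pct_avatar", "pct_near", "pct_room")) {
    cmp <- suppressMessages(compare_models_aoi(rec, "outcome", aoi))
    expect_equal(cmp$df, 4)
    expect_gte(cmp$chisq, 0)
    expect_equal(nrow(cmp$coefficients), 8)   # 4 base + 4 AOI terms
  }
  expect_error(compare_models_aoi(rec[, -5], "outcome", "pct_avatar"),
               "invalid-argument")
})

test_that("an AOI built into the generator is detected by the comparison", {
  hits <- 0L
  for (r in 1:25) {
    rec <- simulate_trial_records(n_per_group = 40, aoi_focus_effect = 0.05,
                                  sd_residual = 0.5, seed = 900 + r)
    cmp <- suppressMessages(compare_models_aoi(rec, "outcome", "pct_avatar",
                                               coef_table = FALSE))
    hits <- hits + (isTRUE(cmp$p < 0.05))
  }
  expect_gt(hits / 25, 0.8)
})

test_that("post hoc contrasts recover a crossover interaction", {
  # build a crossover: gaze effect positive under focus 1, negative under 2
  rec <- simulate_trial_records(
    n_per_group = 40,
    effects = list(intercept = 0, focus = 3, gaze = 3, interaction = -2),
    sd_participant = 0.1, sd_residual = 0.2, seed = 10)
  fit <- suppressMessages(
    fit_coordination_model(rec, "outcome", transform = "none"))
  ct <- posthoc_contrasts(fit, by = "focus")
  expect_equal(nrow(ct), 2)
  # simple gaze effects: 3 - 2*focus => +1 at focus 1, -1 at focus 2
  expect_equal(ct$estimate[ct$by_level == 1], 1, tolerance = 0.15)
  expect_equal(ct$estimate[ct$by_level == 2], -1, tolerance = 0.15)
  expect_true(all(ct$p_adj < 0.05))
  # degenerate factor
  bad <- fit
  bad$data$gaze <- 1
  expect_error(posthoc_contrasts(bad, by = "focus"), "invalid-argument")
})

test_that("null interactions yield comparable simple effects", {
  sig <- 0L
  for (r in 1:20) {
    rec <- simulate_trial_records(n_per_group = 30, seed = 1200 + r)
    fit <- suppressMessages(
      fit_coordination_model(rec, "outcome", transform = "none"))
    ct <- posthoc_contrasts(fit, by = "focus")
    sig <- sig + any(ct$p_adj < 0.05)
  }
  expect_lte(sig / 20, 0.10)
})

test_that("imposed arm-coupling advantage for direct gaze yields a negative gaze coefficient", {
  # full signal path at generous effect size: coupling(direct) >> coupling(averted)
  one_replicate <- function(rep_seed) {
    n_per_group <- 10
    rows <- list()
    seeds <- dyadsync:::derive_seeds(rep_seed, 4 * n_per_group)
    i <- 0L
    for (g in c(1, 2)) {           # 1 = direct, 2 = averted
      k <- if (g == 1) 2.5 else 0.5
      for (p in seq_len(n_per_group)) {
        pid <- sprintf("g%d_p%02d", g, p)
        for (f in c(1, 2)) {
          i <- i + 1L
          ps <- oscillator_params(4 / 3 + 0.05, coupling_strength = k,
                                  phase_noise_sd = 0.3)
          tr <- generate_dyad_trial(ps, oscillator_params(4 / 3), 45, 50,
                                    seed = seeds[i])
          res <- phase_coordination(preprocess_dyad(tr))
          rows[[i]] <- data.frame(participant_id = pid, focus = f, gaze = g,
                                  rho_fisher = res$rho_fisher)
        }
      }
    }
    rec <- do.call(rbind, rows)
    fit <- suppressMessages(
      fit_coordination_model(rec, "rho_fisher", transform = "none"))
    fit$coefficients$b[fit$coefficients$term == "gaze"]
  }
  bs <- vapply(1:200, function(r) one_replicate(3000 + r), numeric(1))
  expect_gt(mean(bs < 0), 0.95)
})
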