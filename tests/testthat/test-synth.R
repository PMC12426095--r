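test_that("identical seeds and parameters reproduce trials byte-for-byte", {
  p <- oscillator_params(4 / 3, coupling_strength = 1, phase_noise_sd = 0.3,
                         measurement_noise_sd = 1)
  a <- generate_dyad_trial(p, oscillator_params(4 / 3), seed = 7)
  b <- generate_dyad_trial(p, oscillator_params(4 / 3), seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(
    a$participant_arm$samples,
    generate_dyad_trial(p, oscillator_params(4 / 3), seed = 8)$participant_arm$samples))

  g1 <- generate_gaze_stream(45, 50, seed = 3)
  g2 <- generate_gaze_stream(45, 50, seed = 3)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))

  h1 <- generate_head_channel(a, 0.5, seed = 5)
  h2 <- generate_head_channel(a, 0.5, seed = 5)
  expect_identical(serialize(h1, NULL), serialize(h2, NULL))
})

test_that("uncoupled noiseless twins produce identical sinusoids", {
  p <- oscillator_params(4 / 3)
  tr <- generate_dyad_trial(p, p, 45, 50, seed = 1)
  # equal up to floating-point accumulation over the integration
  expect_lt(max(abs(tr$participant_arm$samples - tr$avatar_arm$samples)),
            1e-6)
  expect_length(tr$participant_arm$samples, 45 * 50)
})

test_that("generator rejects invalid arguments", {
  p <- oscillator_params(4 / 3)
  expect_error(oscillator_params(-1), "invalid-argument")
  expect_error(oscillator_params(1, coupling_strength = -0.1),
               "invalid-argument")
  expect_error(generate_dyad_trial(p, p, duration = -5), "invalid-argument")
  expect_error(generate_dyad_trial(p, p, duration = 45, rate = 0),
               "invalid-argument")
  # fewer than 4 cycles of the slower oscillator
  expect_error(generate_dyad_trial(oscillator_params(0.05), p, 45, 50),
               "insufficient-data")
})

test_that("detuned uncoupled oscillators sweep phase and give rho near 0", {
  ps <- oscillator_params(1.33)
  pp <- oscillator_params(1.40)
  tr <- generate_dyad_trial(ps, pp, 90, 50, seed = 2)
  pre <- preprocess_dyad(tr, discard = 5, keep = 80)
  res <- phase_coordination(pre)
  expect_lt(res$rho, 0.1)
  # relative phase drifts through the full circle at ~360 * detuning deg/s
  signed <- relative_phase(pre$participant_arm, pre$avatar_arm)
  expect_gt(diff(range(signed)), 300)
})

test_that("phase locking obeys the analytic bound k >= 2*pi*detuning", {
  # 20 (k, detuning) pairs straddling the bound by 15%; zero noise
  set.seed(10)
  for (i in 1:20) {
    df <- runif(1, 0.03, 0.15)
    locked <- i %% 2 == 0
    k <- 2 * pi * df * if (locked) 1.15 else 0.85
    ps <- oscillator_params(4 / 3 + df, coupling_strength = k)
    pp <- oscillator_params(4 / 3)
    tr <- generate_dyad_trial(ps, pp, 60, 50, seed = 100 + i)
    rho <- phase_coordination(preprocess_dyad(tr, keep = 50))$rho
    if (locked) expect_gt(rho, 0.9) else expect_lt(rho, 0.9)
  }
  # far above the bound the lock is essentially perfect
  tr <- generate_dyad_trial(
    oscillator_params(1.33, coupling_strength = 10), oscillator_params(1.40),
    60, 50, seed = 99)
  expect_gt(phase_coordination(preprocess_dyad(tr, keep = 50))$rho, 0.99)
})

test_that("head channels are independent at zero coupling and copies at the limit", {
  ccs <- vapply(1:100, function(s) {
    tr <- generate_dyad_trial(oscillator_params(4 / 3),
                              oscillator_params(4 / 3), 45, 50, seed = s)
    tr <- generate_head_channel(tr, 0, seed = s + 10000)
    cor(tr$participant_head$samples, tr$avatar_head$samples)
  }, numeric(1))
  expect_lt(abs(mean(ccs)), 0.05)

  tr <- generate_dyad_trial(oscillator_params(4 / 3),
                            oscillator_params(4 / 3), 45, 50, seed = 4)
  tr <- generate_head_channel(tr, Inf, seed = 6)
  expect_identical(tr$participant_head$samples, tr$avatar_head$samples)
  pre <- preprocess_dyad(tr)
  res <- crqa_trial(pre, delay = 20, dimension = 5, radius = 12)
  a <- embed_series(pre$avatar_head, 20, 5)
  expect_equal(res$percent_recurrence,
               cross_recurrence(a, a, radius = 12)$percent_recurrence)
})

test_that("head channels carry their spectral mass below the arm rhythm", {
  tr <- generate_dyad_trial(oscillator_params(4 / 3),
                            oscillator_params(4 / 3), 45, 50, seed = 12)
  tr <- generate_head_channel(tr, 0.5, seed = 13)
  for (ch in c("participant_head", "avatar_head")) {
    x <- tr[[ch]]$samples
    pspec <- Mod(fft(x - mean(x)))^2
    freqs <- (seq_along(pspec) - 1) * 50 / length(pspec)
    half <- freqs <= 25
    low <- sum(pspec[half & freqs < 1.2]) / sum(pspec[half])
    expect_gt(low, 0.9)
  }
  expect_error(
    generate_head_channel(tr, -1, seed = 1), "invalid-argument")
})

test_that("gaze streams follow the requested AOI distribution", {
  g <- generate_gaze_stream(60, 50, aoi_probs = c(1, 0, 0), seed = 1)
  expect_true(all(g$labels == "avatar"))

  g <- generate_gaze_stream(10000, 50, aoi_probs = c(0.5, 0.3, 0.2),
                            mean_dwell = 0.5, seed = 2)
  props <- table(factor(g$labels, c("avatar", "near_avatar", "room"))) /
    length(g$labels)
  expect_lt(max(abs(as.numeric(props) - c(0.5, 0.3, 0.2))), 0.01)

  expect_error(generate_gaze_stream(10, 50, aoi_probs = c(0.5, 0.3, 0.3)),
               "invalid-argument")
  expect_error(generate_gaze_stream(10, 50, mean_dwell = 0),
               "invalid-argument")
})

test_that("experiment layout counterbalances focus order within gaze groups", {
  ex <- generate_experiment(experiment_design(n_per_group = 2, seed = 5))
  dt <- ex$design_table
  expect_equal(length(unique(dt$participant_id)), 4)
  expect_equal(nrow(dt), 8)
  expect_length(ex$trials, 8)
  # gaze constant within participant, focus takes both levels
  for (p in unique(dt$participant_id)) {
    sub <- dt[dt$participant_id == p, ]
    expect_equal(length(unique(sub$gaze_condition)), 1)
    expect_setequal(sub$focus_condition, c("self", "other"))
  }
  # each first-trial focus used twice
  first <- dt$focus_condition[dt$trial_order == 1]
  expect_equal(sum(first == "self"), 2)
  expect_equal(sum(first == "other"), 2)
  # per-cell coupling map validation
  expect_error(experiment_design(arm_coupling = c(self_direct = 1)),
               "invalid-argument")
  expect_error(experiment_design(head_coupling = c(
    self_direct = -1, self_averted = 1, other_direct = 1, other_averted = 1)),
    "invalid-argument")
})
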