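# Synthetic dyad generator: stochastic coupled phase oscillators for the
# rhythmic arm channels, band-limited noise for the head channels, and a
# semi-Markov renewal process for area-of-interest gaze labels.

#' Oscillator parameters for one actor's rhythmic arm movement
#'
#' The arm channel is modelled as a first-order stochastic phase oscillator
#' (Kuramoto-type) observed through a sinusoidal readout: the phase advances
#' at the natural frequency, is optionally pulled toward the partner's phase
#' with strength `coupling_strength` (unidirectional, partner to self), and is
#' perturbed by Wiener phase noise. The recorded position is
#' `amplitude * sin(phase)` plus white measurement noise.
#'
#' @param natural_frequency preferred movement frequency in Hz (cycles per
#'   second); must be positive. The movement task paces actors at 80 beats
#'   per minute, i.e. 4/3 Hz.
#' @param amplitude peak displacement in signal units (defaults mimic a hand
#'   tracker reporting millimetres; an arm curl moves the hand ~100 mm about
#'   its mean position).
#' @param coupling_strength phase-attraction strength (1/s), dimensionless in
#'   units of radian pull per radian offset per second; must be >= 0. Zero
#'   means the actor ignores the partner entirely.
#' @param phase_noise_sd standard deviation of the Wiener phase noise in
#'   radians per sqrt(second); >= 0.
#' @param measurement_noise_sd white observation noise, signal units; >= 0.
#' @param initial_phase starting phase in radians.
#' @return an object of class `oscillator_params`.
#' @export
oscillator_params <- function(natural_frequency = 4 / 3,
                              amplitude = 100,
                              coupling_strength = 0,
                              phase_noise_sd = 0,
                              measurement_noise_sd = 0,
                              initial_phase = 0) {
  if (!is.numeric(natural_frequency) || natural_frequency <= 0) {
    stop_invalid("`natural_frequency` must be > 0")
  }
  if (coupling_strength < 0) stop_invalid("`coupling_strength` must be >= 0")
  if (phase_noise_sd < 0 || measurement_noise_sd < 0) {
    stop_invalid("noise standard deviations must be >= 0")
  }
  structure(
    list(
      natural_frequency = natural_frequency,
      amplitude = amplitude,
      coupling_strength = coupling_strength,
      phase_noise_sd = phase_noise_sd,
      measurement_noise_sd = measurement_noise_sd,
      initial_phase = initial_phase
    ),
    class = "oscillator_params"
  )
}

#' One motion channel of one actor in one trial
#'
#' The atomic object all signal operations consume: a uniformly sampled
#' series plus actor/channel/axis metadata.
#'
#' @param samples numeric vector, signal units, no missing values.
#' @param rate sampling rate in samples per second; must be positive.
#' @param actor `"participant"` or `"avatar"`.
#' @param channel `"arm"` or `"head"`.
#' @param axis `"vertical"`, `"anterior_posterior"` or `"lateral"`.
#' @param meta named list of trial metadata (ids, conditions).
#' @return an object of class `movement_trial`.
#' @export
movement_trial <- function(samples, rate, actor = "participant",
                           channel = "arm", axis = "vertical",
                           meta = list()) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_invalid("`rate` must be a single positive number")
  }
  if (anyNA(samples)) stop_invalid("`samples` must not contain missing values")
  actor <- match.arg(actor, c("participant", "avatar"))
  channel <- match.arg(channel, c("arm", "head"))
  axis <- match.arg(axis, c("vertical", "anterior_posterior", "lateral"))
  structure(
    list(samples = as.numeric(samples), rate = rate, actor = actor,
         channel = channel, axis = axis, meta = meta),
    class = "movement_trial"
  )
}

#' @export
print.movement_trial <- function(x, ...) {
  cat(sprintf("<movement_trial> %s %s (%s): %d samples @ %g Hz\n",
              x$actor, x$channel, x$axis, length(x$samples), x$rate))
  invisible(x)
}

#' Generate one dyad trial of coupled rhythmic arm movement
#'
#' Integrates two stochastic phase oscillators with the Euler-Maruyama scheme
#' at the sampling interval. The partner (avatar) evolves uncoupled — it is
#' pre-programmed and unaffected by the self actor — while the self
#' (participant) phase is pulled toward the partner phase with strength
#' `params_self$coupling_strength`:
#' `dtheta_self = (2*pi*f_self + k * sin(theta_partner - theta_self)) dt + noise`.
#'
#' @param params_self,params_partner [oscillator_params()] for the two actors.
#' @param duration trial length in seconds (default 45, matching a 45-s trial).
#' @param rate sampling rate in samples per second (default 50).
#' @param seed integer seed; identical seeds give identical output.
#' @param meta metadata list propagated to both channels.
#' @return a `dyad_trial`: list with `participant_arm` and `avatar_arm`
#'   movement trials, `rate`, `duration`, `meta`.
#' @export
generate_dyad_trial <- function(params_self, params_partner,
                                duration = 45, rate = 50, seed = 1L,
                                meta = list()) {
  stopifnot(inherits(params_self, "oscillator_params"),
            inherits(params_partner, "oscillator_params"))
  if (duration <= 0 || rate <= 0) {
    stop_invalid("`duration` and `rate` must be positive")
  }
  f_slow <- min(params_self$natural_frequency, params_partner$natural_frequency)
  if (duration * f_slow < 4) {
    stop_insufficient("trial must span at least 4 cycles of the slower oscillator")
  }
  n <- round(duration * rate)
  dt <- 1 / rate
  with_seed(seed, {
    # partner first: its realisation never depends on the self oscillator
    noise_p <- rnorm(n, sd = params_partner$phase_noise_sd * sqrt(dt))
    theta_p <- params_partner$initial_phase +
      cumsum(2 * pi * params_partner$natural_frequency * dt + noise_p)
    obs_p <- params_partner$amplitude * sin(theta_p)
    if (params_partner$measurement_noise_sd > 0) {
      obs_p <- obs_p + rnorm(n, sd = params_partner$measurement_noise_sd)
    }

    noise_s <- rnorm(n, sd = params_self$phase_noise_sd * sqrt(dt))
    k <- params_self$coupling_strength
    omega <- 2 * pi * params_self$natural_frequency
    theta_s <- numeric(n)
    th <- params_self$initial_phase
    for (i in seq_len(n)) {
      th <- th + (omega + k * sin(theta_p[i] - th)) * dt + noise_s[i]
      theta_s[i] <- th
    }
    obs_s <- params_self$amplitude * sin(theta_s)
    if (params_self$measurement_noise_sd > 0) {
      obs_s <- obs_s + rnorm(n, sd = params_self$measurement_noise_sd)
    }

    structure(
      list(
        participant_arm = movement_trial(obs_s, rate, "participant", "arm",
                                         "vertical", meta),
        avatar_arm = movement_trial(obs_p, rate, "avatar", "arm",
                                    "vertical", meta),
        rate = rate, duration = duration, meta = meta
      ),
      class = "dyad_trial"
    )
  })
}

#' @export
print.dyad_trial <- function(x, ...) {
  chans <- setdiff(names(x), c("rate", "duration", "meta"))
  cat(sprintf("<dyad_trial> %gs @ %g Hz; channels: %s\n",
              x$duration, x$rate, paste(chans, collapse = ", ")))
  invisible(x)
}

# Band-limited Gaussian head-sway base signal (0.1-1.0 Hz), unit variance.
head_base_signal <- function(n, rate, band = c(0.1, 1.0)) {
  ny <- rate / 2
  bf <- signal::butter(2, band / ny, type = "pass")
  x <- stats::rnorm(n + 4 * rate)           # headroom for filter transients
  y <- signal::filtfilt(bf, x)
  y <- y[(2 * rate + 1):(2 * rate + n)]
  as.numeric((y - mean(y)) / stats::sd(y))
}

#' Add spontaneous head-sway channels to a dyad trial
#'
#' Head movement is emulated as band-limited Gaussian noise (0.1-1.0 Hz),
#' slower and more irregular than the ~1.33 Hz arm rhythm. Unidirectional
#' coupling mixes the avatar's head signal into the participant's:
#' with mixing weight `w = k / (1 + k)` the participant's head is
#' `(1 - w) * own + w * avatar`, renormalised to the head amplitude, so
#' `k = 0` gives statistically independent channels and `k = Inf` the exact
#' copy limit.
#'
#' @param trial a `dyad_trial` with arm channels present.
#' @param coupling_strength unidirectional head coupling, >= 0 (may be `Inf`).
#' @param seed integer seed.
#' @param amplitude head-sway standard deviation in signal units (default 10,
#'   i.e. ~1 cm of anterior-posterior sway).
#' @return the trial with `participant_head` and `avatar_head` channels added.
#' @export
generate_head_channel <- function(trial, coupling_strength = 0, seed = 1L,
                                  amplitude = 10) {
  stopifnot(inherits(trial, "dyad_trial"))
  if (coupling_strength < 0) stop_invalid("`coupling_strength` must be >= 0")
  n <- length(trial$participant_arm$samples)
  if (n != length(trial$avatar_arm$samples)) {
    stop_invalid("arm channels have mismatched lengths")
  }
  rate <- trial$rate
  with_seed(seed, {
    base_a <- head_base_signal(n, rate)
    base_p <- head_base_signal(n, rate)
    w <- if (is.infinite(coupling_strength)) 1 else
      coupling_strength / (1 + coupling_strength)
    mix <- (1 - w) * base_p + w * base_a
    if (w < 1) mix <- mix / sqrt((1 - w)^2 + w^2)
    trial$avatar_head <- movement_trial(amplitude * base_a, rate, "avatar",
                                        "head", "anterior_posterior",
                                        trial$meta)
    trial$participant_head <- movement_trial(amplitude * mix, rate,
                                             "participant", "head",
                                             "anterior_posterior", trial$meta)
    trial
  })
}

#' Generate a per-sample gaze stream over three areas of interest
#'
#' A three-state semi-Markov renewal process: dwell segments have
#' exponentially distributed durations with mean `mean_dwell`, and each
#' segment's AOI is drawn independently from `aoi_probs`, so long-run label
#' proportions converge to `aoi_probs`.
#'
#' @param duration stream length in seconds.
#' @param rate samples per second.
#' @param aoi_probs probabilities for (avatar, near_avatar, room); must sum
#'   to 1 within 1e-9.
#' @param mean_dwell mean fixation dwell per AOI visit, seconds; must be > 0.
#' @param seed integer seed.
#' @param meta metadata list.
#' @return a `gaze_stream`: list with `labels` (character vector), `rate`,
#'   `duration`, `meta`.
#' @export
generate_gaze_stream <- function(duration, rate,
                                 aoi_probs = c(0.6, 0.25, 0.15),
                                 mean_dwell = 2, seed = 1L, meta = list()) {
  if (duration <= 0 || rate <= 0) stop_invalid("duration and rate must be positive")
  if (length(aoi_probs) != 3L || any(aoi_probs < 0) ||
      abs(sum(aoi_probs) - 1) > 1e-9) {
    stop_invalid("`aoi_probs` must be three non-negative values summing to 1")
  }
  if (mean_dwell <= 0) stop_invalid("`mean_dwell` must be > 0")
  aois <- c("avatar", "near_avatar", "room")
  n <- round(duration * rate)
  with_seed(seed, {
    # draw generously more segments than needed, then extend if unlucky
    labels <- character(0)
    remaining <- n
    while (remaining > 0) {
      n_seg <- max(16L, ceiling(remaining / (mean_dwell * rate)) * 2L)
      states <- sample(aois, n_seg, replace = TRUE, prob = aoi_probs)
      lens <- pmax(1L, round(stats::rexp(n_seg, rate = 1 / mean_dwell) * rate))
      labels <- c(labels, rep(states, times = lens))
      remaining <- n - length(labels)
    }
    structure(
      list(labels = labels[seq_len(n)], rate = rate, duration = duration,
           meta = meta),
      class = "gaze_stream"
    )
  })
}

#' Experiment design for a synthetic 2x2 mixed study
#'
#' Focus instruction (self vs. other) varies within participant over two
#' trials with counterbalanced order; avatar gaze (direct vs. averted) is a
#' between-participant factor. Per-cell coupling strengths drive the arm and
#' head generators, and per-focus AOI probabilities drive the gaze generator.
#'
#' Default couplings reproduce the qualitative direction of the study's
#' effects: arm coupling higher under direct than averted gaze (no focus
#' effect), head coupling higher under other- than self-focus, and within
#' other-focus higher under averted than direct gaze.
#'
#' @param n_per_group participants per avatar-gaze group.
#' @param arm_coupling,head_coupling named numeric vectors over the cells
#'   `self_direct`, `self_averted`, `other_direct`, `other_averted`; all
#'   values must be >= 0.
#' @param aoi_probs_self,aoi_probs_other AOI probabilities (avatar, near,
#'   room) under each focus instruction.
#' @param trial_duration seconds (default 45).
#' @param sampling_rate samples per second (default 50).
#' @param phase_noise_sd,freq_sd participant phase noise (rad/sqrt(s)) and
#'   between-participant SD of the natural movement frequency (Hz).
#' @param measurement_noise_sd tracker noise, signal units.
#' @param seed master integer seed for the whole experiment.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(n_per_group = 20,
                              arm_coupling = c(self_direct = 2.0,
                                               self_averted = 0.8,
                                               other_direct = 2.0,
                                               other_averted = 0.8),
                              head_coupling = c(self_direct = 0.3,
                                                self_averted = 0.3,
                                                other_direct = 0.8,
                                                other_averted = 1.4),
                              aoi_probs_self = c(0.45, 0.30, 0.25),
                              aoi_probs_other = c(0.70, 0.20, 0.10),
                              trial_duration = 45,
                              sampling_rate = 50,
                              phase_noise_sd = 0.3,
                              freq_sd = 0.04,
                              measurement_noise_sd = 1,
                              seed = 1L) {
  cells <- c("self_direct", "self_averted", "other_direct", "other_averted")
  if (!all(cells %in% names(arm_coupling)) ||
      !all(cells %in% names(head_coupling))) {
    stop_invalid("coupling maps must name all four design cells")
  }
  if (any(arm_coupling < 0) || any(head_coupling < 0)) {
    stop_invalid("cell couplings must be non-negative")
  }
  if (n_per_group < 1) stop_invalid("`n_per_group` must be >= 1")
  structure(
    list(n_per_group = n_per_group,
         arm_coupling = arm_coupling[cells],
         head_coupling = head_coupling[cells],
         aoi_probs_self = aoi_probs_self, aoi_probs_other = aoi_probs_other,
         trial_duration = trial_duration, sampling_rate = sampling_rate,
         phase_noise_sd = phase_noise_sd, freq_sd = freq_sd,
         measurement_noise_sd = measurement_noise_sd,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Generate a full synthetic 2x2 experiment
#'
#' Each synthetic participant completes two 45-s trials (self- and
#' other-focus) with order counterbalanced across participants; the avatar
#' gaze group is fixed per participant. Per-cell coupling values drive the
#' arm and head generators; per-focus AOI probabilities drive the gaze
#' generator. All randomness descends from `design$seed`.
#'
#' @param design an [experiment_design()].
#' @return list with `design_table` (one row per trial: participant_id,
#'   gaze_condition, trial_id, focus_condition, trial_order), `trials`
#'   (named list of `dyad_trial`s keyed by trial_id) and `gaze` (named list
#'   of `gaze_stream`s).
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n_pp <- 2L * design$n_per_group
  gaze_group <- rep(c("direct", "averted"), each = design$n_per_group)
  # counterbalance: alternate first-focus within each gaze group
  first_focus <- rep_len(c("self", "other"), n_pp)
  pid <- sprintf("P%03d", seq_len(n_pp))

  rows <- list()
  trials <- list()
  gaze_streams <- list()
  seeds <- derive_seeds(design$seed, n_pp * 8L)
  si <- 0L
  nxt <- function() {
    si <<- si + 1L
    seeds[si]
  }

  for (i in seq_len(n_pp)) {
    # stable participant traits across both trials
    f_i <- with_seed(nxt(), stats::rnorm(1, 4 / 3, design$freq_sd))
    phase0 <- with_seed(nxt(), stats::runif(1, 0, 2 * pi))
    focus_order <- if (first_focus[i] == "self") c("self", "other") else
      c("other", "self")
    for (j in 1:2) {
      focus <- focus_order[j]
      cell <- paste(focus, gaze_group[i], sep = "_")
      trial_id <- sprintf("%s_T%d", pid[i], j)
      meta <- list(participant_id = pid[i], trial_id = trial_id,
                   focus = focus, gaze = gaze_group[i], trial_order = j)
      p_self <- oscillator_params(
        natural_frequency = max(f_i, 0.5),
        coupling_strength = design$arm_coupling[[cell]],
        phase_noise_sd = design$phase_noise_sd,
        measurement_noise_sd = design$measurement_noise_sd,
        initial_phase = phase0
      )
      p_avatar <- oscillator_params(
        natural_frequency = 4 / 3,
        measurement_noise_sd = design$measurement_noise_sd
      )
      tr <- generate_dyad_trial(p_self, p_avatar, design$trial_duration,
                                design$sampling_rate, seed = nxt(),
                                meta = meta)
      tr <- generate_head_channel(tr, design$head_coupling[[cell]],
                                  seed = nxt())
      probs <- if (focus == "self") design$aoi_probs_self else
        design$aoi_probs_other
      gs <- generate_gaze_stream(design$trial_duration, design$sampling_rate,
                                 aoi_probs = probs, seed = nxt(), meta = meta)
      trials[[trial_id]] <- tr
      gaze_streams[[trial_id]] <- gs
      rows[[trial_id]] <- data.frame(
        participant_id = pid[i], gaze_condition = gaze_group[i],
        trial_id = trial_id, focus_condition = focus, trial_order = j,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    design_table = do.call(rbind, c(rows, make.row.names = FALSE)),
    trials = trials,
    gaze = gaze_streams
  )
}
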