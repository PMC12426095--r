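# Relative-phase coordination of the rhythmic arm channels: analytic-signal
# phase, signed and folded relative phase, and the circular stability
# statistic rho with its Fisher transform.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes the negative-frequency half of the spectrum and doubles the
#' positive half, so the imaginary part of the result is the Hilbert
#' transform of the input.
#'
#' @param x real numeric vector (should be zero-mean and band-limited).
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a movement series
#'
#' Computes the unwrapped analytic-signal phase. For a noiseless rhythmic
#' input the result increases monotonically at the movement frequency.
#'
#' @param trial a preprocessed (centred, band-limited) [movement_trial()].
#' @param amplitude_floor envelope floor in signal units: if the median
#'   analytic envelope falls below it the result carries a
#'   `low_amplitude = TRUE` attribute (phase is still returned). Default 0
#'   (never flags).
#' @return numeric vector of unwrapped phase in radians, with attributes
#'   `envelope_median` and `low_amplitude`.
#' @export
instantaneous_phase <- function(trial, amplitude_floor = 0) {
  stopifnot(inherits(trial, "movement_trial"))
  x <- trial$samples
  if (all(x == 0) || stats::sd(x) == 0) {
    stop("degenerate-signal: input has zero variance", call. = FALSE)
  }
  z <- analytic_signal(x - mean(x))
  ph <- signal::unwrap(Arg(z))
  env_med <- stats::median(Mod(z))
  attr(ph, "envelope_median") <- env_med
  attr(ph, "low_amplitude") <- env_med < amplitude_floor
  ph
}

#' Signed relative phase between two arm series
#'
#' Pointwise difference of the actors' instantaneous phases
#' (participant minus avatar), wrapped to (-180, 180] degrees.
#'
#' @param participant_arm,avatar_arm preprocessed [movement_trial()]s of
#'   equal length and rate.
#' @return numeric vector of signed relative phase in degrees.
#' @export
relative_phase <- function(participant_arm, avatar_arm) {
  stopifnot(inherits(participant_arm, "movement_trial"),
            inherits(avatar_arm, "movement_trial"))
  if (length(participant_arm$samples) != length(avatar_arm$samples)) {
    stop_invalid("series lengths differ")
  }
  if (participant_arm$rate != avatar_arm$rate) {
    stop_invalid("sampling rates differ")
  }
  d <- as.numeric(instantaneous_phase(participant_arm)) -
    as.numeric(instantaneous_phase(avatar_arm))
  wrap_degrees(d * 180 / pi)
}

#' Fold signed relative phase onto [0, 180] degrees
#'
#' Takes the absolute value: 0 is in-phase, 180 anti-phase; lead and lag are
#' not distinguished.
#'
#' @param signed_phase signed relative phase in degrees, in (-180, 180].
#' @return folded phase in degrees, in \[0, 180\].
#' @export
fold_phase <- function(signed_phase) abs(signed_phase)

#' Coordination stability (rho) of a folded relative-phase distribution
#'
#' Rho is the mean resultant length of the relative-phase distribution — a
#' linear index of coordination stability in which higher values mean more
#' stable coordination (rho = 1 - circular variance). Because folded phase
#' lives on a half-circle, the default `"doubled"` mode doubles the angles
#' before computing the resultant (the axial-data convention), so a folded
#' distribution that is uniform on \[0, 180\] maps to rho near 0; the
#' `"resultant"` mode uses the angles as-is.
#'
#' @param folded folded relative phase in degrees, in \[0, 180\].
#' @param mode `"doubled"` (default, axial convention) or `"resultant"`.
#' @param clamp_eps clamp applied before the Fisher transform:
#'   `rho_fisher = atanh(min(rho, 1 - clamp_eps))` stays finite for perfectly
#'   locked trials. Default 1e-6.
#' @return an object of class `phase_result`: list with `relative_phase`
#'   (the folded series), `rho`, `rho_fisher`, `circular_variance`
#'   (`1 - rho`), `n_samples` and `mode`.
#' @export
coordination_rho <- function(folded, mode = c("doubled", "resultant"),
                             clamp_eps = 1e-6) {
  mode <- match.arg(mode)
  n <- length(folded)
  if (n < 100) stop_insufficient("rho requires at least 100 phase samples")
  ang <- folded * pi / 180
  mult <- if (mode == "doubled") 2 else 1
  rho <- Mod(mean(exp(1i * mult * ang)))
  structure(
    list(relative_phase = folded,
         rho = rho,
         rho_fisher = atanh(min(rho, 1 - clamp_eps)),
         circular_variance = 1 - rho,
         n_samples = n,
         mode = mode),
    class = "phase_result"
  )
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result> rho = %.4f (Fisher %.4f), n = %d, mode = %s\n",
              x$rho, x$rho_fisher, x$n_samples, x$mode))
  invisible(x)
}

#' Arm-coordination stability for one dyad trial
#'
#' Runs the full relative-phase chain on the preprocessed arm channels:
#' Hilbert phases, signed difference wrapped to (-180, 180], folding to
#' \[0, 180\], edge exclusion, and rho with its Fisher transform. The first
#' and last `edge_trim` seconds are excluded from rho to avoid analytic-signal
#' end effects.
#'
#' @param trial a preprocessed `dyad_trial` with arm channels.
#' @param mode passed to [coordination_rho()].
#' @param edge_trim seconds excluded at each end (default 1).
#' @return a `phase_result` (see [coordination_rho()]).
#' @export
phase_coordination <- function(trial, mode = c("doubled", "resultant"),
                               edge_trim = 1) {
  stopifnot(inherits(trial, "dyad_trial"))
  mode <- match.arg(mode)
  signed <- relative_phase(trial$participant_arm, trial$avatar_arm)
  folded <- fold_phase(signed)
  n <- length(folded)
  k <- round(edge_trim * trial$rate)
  if (n - 2 * k < 100) stop_insufficient("too few interior samples for rho")
  coordination_rho(folded[(k + 1):(n - k)], mode = mode)
}
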