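# Preprocessing: trim the movement-initiation transient, standardise trial
# length, centre, and low-pass filter with a zero-phase Butterworth.

#' Trim the initial transient and standardise trial length
#'
#' Discards the first `discard` seconds (movement initiation) and keeps
#' exactly `keep` seconds: the output has `keep * rate` samples starting
#' `discard` seconds into the input. No resampling is performed.
#'
#' @param trial a [movement_trial()].
#' @param discard seconds to drop from the start (default 5).
#' @param keep standardised length in seconds (default 40).
#' @return the trimmed `movement_trial`.
#' @export
trim_and_standardize <- function(trial, discard = 5, keep = 40) {
  stopifnot(inherits(trial, "movement_trial"))
  if (discard < 0 || keep <= 0) stop_invalid("`discard` >= 0 and `keep` > 0 required")
  n_discard <- round(discard * trial$rate)
  n_keep <- round(keep * trial$rate)
  if (length(trial$samples) < n_discard + n_keep) {
    id <- trial$meta$trial_id %||% "<unknown>"
    stop_insufficient(sprintf(
      "trial %s has %d samples; %d required (discard %gs + keep %gs at %g Hz)",
      id, length(trial$samples), n_discard + n_keep, discard, keep, trial$rate))
  }
  trial$samples <- trial$samples[(n_discard + 1):(n_discard + n_keep)]
  trial
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extend a centred series at both ends by autoregressive (Burg)
# extrapolation, which continues band-limited rhythmic signals almost
# exactly and so leaves no joint discontinuity for the filter to ring on.
# Falls back to constant extension for degenerate (near-constant) input.
ar_extend <- function(x, pad, max_order = 30) {
  n <- length(x)
  ord <- min(max_order, n - 1, floor(n / 3))
  fit <- if (ord >= 1 && stats::sd(x) > 0) {
    tryCatch(stats::ar(x, aic = FALSE, order.max = ord, method = "burg"),
             error = function(e) NULL)
  }
  if (is.null(fit) || length(fit$ar) == 0) {
    return(c(rep(x[1], pad), x, rep(x[n], pad)))
  }
  extend <- function(v) {
    a <- fit$ar
    vb <- v - fit$x.mean
    buf <- rev(vb[(length(vb) - length(a) + 1):length(vb)])
    out <- numeric(pad)
    for (i in seq_len(pad)) {
      nx <- sum(a * buf)
      out[i] <- nx
      buf <- c(nx, buf[-length(buf)])
    }
    out + fit$x.mean
  }
  c(rev(extend(rev(x))), x, extend(x))
}

#' Centre a movement series and low-pass filter it (zero phase)
#'
#' Subtracts the mean, applies a Butterworth low-pass forward and backward
#' (zero net phase shift; the magnitude response is squared), then re-centres
#' to remove any residual edge-induced offset. Before filtering the series is
#' extended at both ends by autoregressive extrapolation so the filter
#' transient falls entirely outside the retained samples.
#'
#' @param trial a [movement_trial()].
#' @param cutoff low-pass cutoff in Hz (default 10); must be below Nyquist.
#' @param order Butterworth order per pass (default 4; the bidirectional
#'   magnitude response is effectively 8th order).
#' @return the centred, filtered `movement_trial` (length preserved).
#' @export
center_and_filter <- function(trial, cutoff = 10, order = 4) {
  stopifnot(inherits(trial, "movement_trial"))
  ny <- trial$rate / 2
  if (cutoff >= ny) stop_invalid("`cutoff` must be below the Nyquist frequency")
  if (cutoff <= 0) stop_invalid("`cutoff` must be positive")
  x <- trial$samples - mean(trial$samples)
  n <- length(x)
  # two seconds of extrapolated signal comfortably outlast the transient
  pad <- max(3L * order, round(2 * trial$rate))
  xe <- ar_extend(x, pad)
  bf <- signal::butter(order, cutoff / ny, type = "low")
  ye <- signal::filtfilt(bf, xe)
  y <- ye[(pad + 1):(pad + n)]
  trial$samples <- y - mean(y)
  trial
}

#' Preprocess every channel of a dyad trial
#'
#' Applies [trim_and_standardize()] then [center_and_filter()] to each
#' movement channel, in that order.
#'
#' @param trial a `dyad_trial`.
#' @inheritParams trim_and_standardize
#' @inheritParams center_and_filter
#' @return the preprocessed `dyad_trial`.
#' @export
preprocess_dyad <- function(trial, discard = 5, keep = 40, cutoff = 10,
                            order = 4) {
  stopifnot(inherits(trial, "dyad_trial"))
  for (nm in names(trial)) {
    if (inherits(trial[[nm]], "movement_trial")) {
      trial[[nm]] <- center_and_filter(
        trim_and_standardize(trial[[nm]], discard, keep), cutoff, order)
    }
  }
  trial$duration <- keep
  trial
}

#' Trim a gaze stream to the motion analysis window
#'
#' Aligns gaze with the post-trim motion window: drops the first `discard`
#' seconds and keeps `keep` seconds of labels.
#'
#' @param stream a `gaze_stream`.
#' @inheritParams trim_and_standardize
#' @return the trimmed `gaze_stream`.
#' @export
trim_gaze <- function(stream, discard = 5, keep = 40) {
  stopifnot(inherits(stream, "gaze_stream"))
  n_discard <- round(discard * stream$rate)
  n_keep <- round(keep * stream$rate)
  if (length(stream$labels) < n_discard + n_keep) {
    stop_insufficient("gaze stream shorter than discard + keep window")
  }
  stream$labels <- stream$labels[(n_discard + 1):(n_discard + n_keep)]
  stream$duration <- keep
  stream
}
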