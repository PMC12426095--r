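# Gaze reduction: per-sample AOI labels to per-trial percentage dwell times.

#' Summarise a gaze stream into AOI dwell-time percentages
#'
#' Computes the percentage of valid (non-missing) samples spent on each of
#' the three areas of interest: the avatar, near the avatar, and the rest of
#' the room. Missing samples (blinks, tracking loss) are excluded from the
#' denominator; trials whose valid fraction falls below `min_valid` are
#' flagged unusable rather than silently dropped.
#'
#' @param stream a `gaze_stream` whose labels are in
#'   `c("avatar", "near_avatar", "room", "missing")`.
#' @param min_valid minimum proportion of valid samples for the trial to be
#'   usable (default 0.5).
#' @return an object of class `gaze_summary`: list with `pct_avatar`,
#'   `pct_near`, `pct_room` (percentages over valid samples),
#'   `valid_fraction`, and `usable` (logical).
#' @export
summarize_gaze <- function(stream, min_valid = 0.5) {
  stopifnot(inherits(stream, "gaze_stream"))
  labels <- stream$labels
  if (!length(labels)) stop_invalid("gaze stream is empty")
  known <- c("avatar", "near_avatar", "room", "missing")
  if (!all(labels %in% known)) {
    stop_invalid("unknown AOI labels: ",
                 paste(setdiff(unique(labels), known), collapse = ", "))
  }
  valid <- labels != "missing"
  n_valid <- sum(valid)
  if (n_valid == 0) {
    stop("no-valid-gaze: every sample is missing", call. = FALSE)
  }
  counts <- c(avatar = sum(labels == "avatar"),
              near_avatar = sum(labels == "near_avatar"),
              room = sum(labels == "room"))
  pct <- 100 * counts / n_valid
  structure(
    list(pct_avatar = unname(pct["avatar"]),
         pct_near = unname(pct["near_avatar"]),
         pct_room = unname(pct["room"]),
         valid_fraction = n_valid / length(labels),
         usable = n_valid / length(labels) >= min_valid),
    class = "gaze_summary"
  )
}

#' @export
print.gaze_summary <- function(x, ...) {
  cat(sprintf(
    "<gaze_summary> avatar %.1f%% | near %.1f%% | room %.1f%% (valid %.0f%%%s)\n",
    x$pct_avatar, x$pct_near, x$pct_room, 100 * x$valid_fraction,
    if (x$usable) "" else ", UNUSABLE"))
  invisible(x)
}
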