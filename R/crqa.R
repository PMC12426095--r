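# Cross-recurrence quantification of the head channels: data-driven
# embedding parameters (AMI first minimum for the delay, FNN first minimum
# for the dimension), radius-thresholded cross-recurrence, and %REC.

as_series <- function(x) {
  if (inherits(x, "movement_trial")) x$samples else as.numeric(x)
}

#' Average mutual information between a series and its lagged copy
#'
#' Histogram (equal-width binning) estimator in bits. `ami[1]` is the lag-0
#' value, i.e. the marginal entropy estimate of the binned series.
#'
#' @param series numeric vector or [movement_trial()].
#' @param max_lag largest lag in samples.
#' @param n_bins number of histogram bins; default `ceiling(sqrt(n))` capped
#'   at 16 (a tighter cap keeps the AMI curve of strongly deterministic
#'   signals smooth enough for reliable first-minimum detection).
#' @return numeric vector of length `max_lag + 1`: AMI at lags `0..max_lag`.
#' @export
average_mutual_information <- function(series, max_lag, n_bins = NULL) {
  x <- as_series(series)
  n <- length(x)
  if (n <= 2 * max_lag) stop_insufficient("series length must exceed 2 * max_lag")
  if (is.null(n_bins)) n_bins <- min(16L, ceiling(sqrt(n)))
  if (n_bins < 2) stop_invalid("`n_bins` must be >= 2")
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate-signal: constant series", call. = FALSE)
  bins <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  vapply(0:max_lag, function(lag) {
    a <- bins[seq_len(n - lag)]
    b <- bins[seq_len(n - lag) + lag]
    joint <- table(a, b) / (n - lag)
    px <- rowSums(joint)
    py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / (px[row(joint)[nz]] * py[col(joint)[nz]])))
  }, numeric(1))
}

#' Select the embedding delay from an AMI curve
#'
#' Returns the smallest lag `tau >= 1` that is a first local minimum of the
#' AMI curve (`AMI(tau) < AMI(tau - 1)` and `AMI(tau) <= AMI(tau + 1)`). If
#' the curve has no interior minimum the maximal lag is returned with a
#' `no_minimum` flag.
#'
#' @param ami_curve numeric vector as returned by
#'   [average_mutual_information()] (`ami_curve[1]` is lag 0).
#' @return list with `delay` (samples) and `no_minimum` (logical).
#' @export
select_delay <- function(ami_curve) {
  if (length(ami_curve) < 3) stop_invalid("AMI curve must cover lags 0..2 at least")
  max_lag <- length(ami_curve) - 1L
  for (tau in 1:(max_lag - 1L)) {
    if (ami_curve[tau + 1] < ami_curve[tau] &&
        ami_curve[tau + 1] <= ami_curve[tau + 2]) {
      return(list(delay = tau, no_minimum = FALSE))
    }
  }
  list(delay = max_lag, no_minimum = TRUE)
}

#' Time-delay embedding
#'
#' @param series numeric vector or [movement_trial()].
#' @param delay lag in samples (>= 1).
#' @param dimension embedding dimension (>= 1).
#' @return matrix with `n - (dimension - 1) * delay` rows; row `i` is
#'   `(x_i, x_{i + delay}, ..., x_{i + (dimension - 1) * delay})`.
#' @export
embed_series <- function(series, delay, dimension) {
  x <- as_series(series)
  if (delay < 1 || dimension < 1) stop_invalid("delay and dimension must be >= 1")
  n <- length(x)
  n_emb <- n - (dimension - 1) * delay
  if (n_emb < 2) stop_insufficient("series too short to embed at these parameters")
  out <- matrix(0, n_emb, dimension)
  for (d in seq_len(dimension)) {
    out[, d] <- x[seq_len(n_emb) + (d - 1) * delay]
  }
  out
}

# Centred moving average with shrinking windows at the edges.
smooth_curve <- function(x, window = 3) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Squared Euclidean cross-distance matrix (vectorised).
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' False-nearest-neighbour fractions per embedding dimension
#'
#' For each dimension `m` in `1..max_dim`, each point's nearest neighbour in
#' the `m`-dimensional embedding is found and judged false if adding the
#' `(m + 1)`-th coordinate grows the distance by more than `r_tol` relative
#' to the `m`-dimensional distance, or if the grown distance exceeds `a_tol`
#' times the series standard deviation (the two standard criteria).
#'
#' @param series numeric vector or [movement_trial()].
#' @param delay embedding delay in samples.
#' @param max_dim largest dimension examined (default 10).
#' @param r_tol distance-growth ratio tolerance (default 10).
#' @param a_tol attractor-size tolerance (default 2).
#' @return numeric vector of FNN fractions for dimensions `1..max_dim`, with
#'   attribute `degenerate` set when the series has zero variance.
#' @export
false_nearest_neighbours <- function(series, delay, max_dim = 10,
                                     r_tol = 10, a_tol = 2) {
  x <- as_series(series)
  n <- length(x)
  if (n - max_dim * delay < 50) {
    stop_insufficient("series too short for FNN up to max_dim at this delay")
  }
  sd_x <- stats::sd(x)
  if (sd_x == 0) {
    out <- rep(0, max_dim)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fractions <- numeric(max_dim)
  for (m in seq_len(max_dim)) {
    # restrict to points whose (m+1)-th coordinate exists
    n_eff <- n - m * delay
    emb <- embed_series(x[seq_len(n - delay)], delay, m)[seq_len(n_eff), ,
                                                         drop = FALSE]
    d2 <- cross_dist2(emb, emb)
    diag(d2) <- Inf
    nn <- max.col(-d2, ties.method = "first")
    rm2 <- d2[cbind(seq_len(n_eff), nn)]
    rm <- sqrt(rm2)
    extra <- abs(x[seq_len(n_eff) + m * delay] - x[nn + m * delay])
    rm1 <- sqrt(rm2 + extra^2)
    # floor the denominator: exact orbit repeats (rm ~ machine eps) are true
    # neighbours, not ratios of rounding noise
    crit1 <- extra > r_tol * pmax(rm, 1e-8 * sd_x)
    crit2 <- rm1 / sd_x > a_tol
    fractions[m] <- mean(crit1 | crit2)
  }
  attr(fractions, "degenerate") <- FALSE
  fractions
}

#' Select the embedding dimension from an FNN curve
#'
#' Returns the smaller of: the first dimension whose FNN fraction drops below
#' 1%, and the first local minimum of the curve. If neither occurs before
#' `max_dim`, returns `max_dim` with a `no_minimum` flag.
#'
#' @param fnn_curve numeric vector of FNN fractions for dimensions `1..m`.
#' @return list with `dimension` and `no_minimum` (logical).
#' @export
select_dimension <- function(fnn_curve) {
  m_max <- length(fnn_curve)
  if (m_max < 1) stop_invalid("FNN curve is empty")
  below <- which(fnn_curve < 0.01)
  m_sub <- if (length(below)) below[1] else NA_integer_
  m_loc <- NA_integer_
  if (m_max >= 3) {
    for (m in 2:(m_max - 1)) {
      if (fnn_curve[m] < fnn_curve[m - 1] && fnn_curve[m] <= fnn_curve[m + 1]) {
        m_loc <- m
        break
      }
    }
  }
  cand <- c(m_sub, m_loc)
  cand <- cand[!is.na(cand)]
  if (length(cand)) {
    list(dimension = min(cand), no_minimum = FALSE)
  } else {
    list(dimension = m_max, no_minimum = TRUE)
  }
}

#' Estimate embedding parameters from one or more reference series
#'
#' Follows the standard protocol: the delay is the first minimum of the
#' average mutual information and the dimension the first minimum of the
#' false-nearest-neighbour fractions. When several series are supplied
#' (pooled estimation across trials), their AMI and FNN curves are averaged
#' before the minima are located. In the study design the avatar's series is
#' the reference.
#'
#' Histogram AMI estimates carry sampling wiggles of a few thousandths of a
#' bit, enough to trip a strict first-dip rule on an otherwise smoothly
#' decreasing curve; the averaged AMI curve is therefore smoothed with a
#' short centred moving average (`ami_smooth` points) before the first
#' minimum is located. Set `ami_smooth = 1` to disable.
#'
#' @param series_list a numeric vector / `movement_trial`, or a list of them.
#' @param rate sampling rate (samples/second), used for the default max lag.
#' @param max_lag largest AMI lag in samples; default 2 seconds of samples.
#' @param max_dim largest FNN dimension (default 10).
#' @param n_bins passed to [average_mutual_information()].
#' @param ami_smooth odd moving-average window applied to the AMI curve
#'   before minimum detection (default 3; 1 disables).
#' @param r_tol,a_tol passed to [false_nearest_neighbours()].
#' @return list with `delay`, `dimension`, `ami` (mean curve), `fnn` (mean
#'   curve), and flags `delay_no_minimum`, `dimension_no_minimum`.
#' @export
estimate_embedding <- function(series_list, rate, max_lag = round(2 * rate),
                               max_dim = 10, n_bins = NULL, ami_smooth = 3,
                               r_tol = 10, a_tol = 2) {
  if (!is.list(series_list) || inherits(series_list, "movement_trial")) {
    series_list <- list(series_list)
  }
  ami <- Reduce(`+`, lapply(series_list, average_mutual_information,
                            max_lag = max_lag, n_bins = n_bins)) /
    length(series_list)
  sel_d <- select_delay(smooth_curve(ami, ami_smooth))
  fnn <- Reduce(`+`, lapply(series_list, false_nearest_neighbours,
                            delay = sel_d$delay, max_dim = max_dim,
                            r_tol = r_tol, a_tol = a_tol)) /
    length(series_list)
  sel_m <- select_dimension(as.numeric(fnn))
  list(delay = sel_d$delay, dimension = sel_m$dimension,
       ami = ami, fnn = as.numeric(fnn),
       delay_no_minimum = sel_d$no_minimum,
       dimension_no_minimum = sel_m$no_minimum)
}

#' Cross-recurrence between two embedded trajectories
#'
#' Counts the cell pairs of the cross-recurrence matrix whose Euclidean
#' inter-trajectory distance is within `radius`, over the full matrix (no
#' diagonal exclusion: distinct series have no trivial identity line), and
#' reports percent recurrence.
#'
#' @param a,b embedded point matrices (rows = points) with equal column
#'   counts, as returned by [embed_series()].
#' @param radius recurrence radius in the signal's native units (default 12).
#' @param norm distance norm; only `"euclidean"` is supported.
#' @return an object of class `crqa_result`: list with `delay`, `dimension`
#'   (taken as `ncol(a)` when not supplied via attributes), `radius`,
#'   `n_embedded` (rows of `a`), `recurrent_points` and
#'   `percent_recurrence` (= 100 * recurrent_points / (n_a * n_b)).
#' @export
cross_recurrence <- function(a, b, radius = 12, norm = "euclidean") {
  norm <- match.arg(norm, "euclidean")
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  if (ncol(a) != ncol(b)) stop_invalid("embedding dimensions differ")
  if (radius <= 0) stop_invalid("`radius` must be positive")
  d2 <- cross_dist2(a, b)
  count <- sum(d2 <= radius^2)
  structure(
    list(dimension = ncol(a), radius = radius, norm = norm,
         n_embedded = nrow(a), n_embedded_b = nrow(b),
         recurrent_points = count,
         percent_recurrence = 100 * count / (nrow(a) * nrow(b))),
    class = "crqa_result"
  )
}

#' @export
print.crqa_result <- function(x, ...) {
  cat(sprintf("<crqa_result> %%REC = %.3f (r = %g, m = %d, n = %d)\n",
              x$percent_recurrence, x$radius, x$dimension, x$n_embedded))
  invisible(x)
}

#' Head-movement cross-recurrence for one dyad trial
#'
#' Embeds the preprocessed participant and avatar head channels with the
#' supplied (or estimated) parameters and computes percent recurrence.
#'
#' @param trial a preprocessed `dyad_trial` with head channels.
#' @param delay,dimension embedding parameters; if either is `NULL` they are
#'   estimated from the avatar head series via [estimate_embedding()].
#' @param radius recurrence radius in signal units (default 12).
#' @return a `crqa_result` with `delay` recorded.
#' @export
crqa_trial <- function(trial, delay = NULL, dimension = NULL, radius = 12) {
  stopifnot(inherits(trial, "dyad_trial"))
  if (is.null(trial$participant_head) || is.null(trial$avatar_head)) {
    stop_invalid("trial has no head channels")
  }
  if (is.null(delay) || is.null(dimension)) {
    est <- estimate_embedding(trial$avatar_head, rate = trial$rate)
    if (is.null(delay)) delay <- est$delay
    if (is.null(dimension)) dimension <- est$dimension
  }
  a <- embed_series(trial$participant_head, delay, dimension)
  b <- embed_series(trial$avatar_head, delay, dimension)
  res <- cross_recurrence(a, b, radius = radius)
  res$delay <- delay
  res
}
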