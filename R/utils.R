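#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so no generator call leaks hidden global state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid-argument: `seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from one master seed
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stop_invalid <- function(...) {
  stop("invalid-argument: ", ..., call. = FALSE)
}

stop_insufficient <- function(...) {
  stop("insufficient-data: ", ..., call. = FALSE)
}

#' Wrap angles in degrees to the half-open interval (-180, 180]
#' @param deg numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_degrees <- function(deg) {
  w <- ((deg %% 360) + 360) %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}
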