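# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eht <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_eht("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_eht("`%s` must be a single non-negative finite number", name)
  invisible(x)
}

#' Run code with a reproducible, isolated RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a single integer seed fully determines the output and
#' the caller's global RNG state is left untouched.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_eht("`seed` must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

# map an angle in degrees to the axial interval [0, 180)
wrap_axial <- function(theta) {
  out <- theta %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

# wrap a difference of doubled angles (degrees) to (-180, 180]
wrap_pm180 <- function(d) {
  d <- (d + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

# linear interpolation of the time at which y crosses `level`,
# scanning from index `from` in direction `dir` (+1/-1); NA if never
cross_time <- function(t, y, level, from, dir = 1L, rising = TRUE) {
  n <- length(y)
  i <- from
  while (i + dir >= 1L && i + dir <= n) {
    j <- i + dir
    hit <- if (rising) (y[i] < level && y[j] >= level) else (y[i] > level && y[j] <= level)
    if (hit) {
      f <- (level - y[i]) / (y[j] - y[i])
      return(t[i] + f * (t[j] - t[i]))
    }
    i <- j
  }
  NA_real_
}
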