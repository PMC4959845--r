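#' Stimulus objects
#'
#' A stimulus is a tibble with columns `time`, `x` (the encoded target
#' variable) and `c` (the feed-forward command driving the network). The two
#' are related by the first-order target dynamics
#' \deqn{\tau \, dx/dt = -x + c,}
#' so that for a constant target the command equals the target, and for a
#' time-varying target the command is recovered by finite differences (see
#' [command_from_target()]).
#'
#' @param x Numeric vector, the target trace.
#' @param tau Readout/membrane time constant in seconds.
#' @param dt Time step in seconds.
#' @param command Optional command trace; computed from `x` when `NULL`.
#' @return A tibble with columns `time`, `x`, `c` and attribute `dt`.
#' @export
as_stimulus <- function(x, tau, dt, command = NULL) {
  if (length(x) < 2L) abort("a stimulus needs at least 2 samples")
  if (is.null(command)) command <- command_from_target(x, tau, dt)
  stopifnot(length(command) == length(x))
  out <- tibble(time = seq_along(x) * dt, x = x, c = command)
  attr(out, "dt") <- dt
  attr(out, "tau") <- tau
  class(out) <- c("stimulus", class(out))
  out
}

#' Constant-target stimulus
#'
#' @param amplitude The constant target value.
#' @param duration Duration in seconds.
#' @param dt Time step in seconds.
#' @param tau Time constant in seconds (the command equals the target for a
#'   constant, so `tau` only annotates the object).
#' @return A stimulus tibble (see [as_stimulus()]).
#' @examples
#' s <- constant_stimulus(50, duration = 1)
#' @export
constant_stimulus <- function(amplitude, duration, dt = 5e-4, tau = 0.1) {
  n <- round(duration / dt)
  as_stimulus(rep(amplitude, n), tau = tau, dt = dt,
              command = rep(amplitude, n))
}

#' Low-pass-filtered white-noise stimulus
#'
#' White noise on the simulation grid is low-pass filtered with a causal
#' first-order Butterworth filter and then affinely rescaled so the realized
#' sample mean and standard deviation match the requested values exactly.
#'
#' @param cutoff_hz Filter cut-off frequency (must be below Nyquist).
#' @param mean,sd Target sample mean and standard deviation of the trace.
#' @param duration Duration in seconds.
#' @param dt Time step in seconds.
#' @param tau Time constant used to derive the command trace.
#' @param filter_order Butterworth order (default 1).
#' @param seed Optional integer seed.
#' @return A stimulus tibble.
#' @export
filtered_noise_stimulus <- function(cutoff_hz, mean = 3, sd = 1,
                                    duration = 10, dt = 5e-4, tau = 0.1,
                                    filter_order = 1, seed = NULL) {
  if (cutoff_hz <= 0) abort("cutoff_hz must be positive")
  fs <- 1 / dt
  if (cutoff_hz >= fs / 2) abort("cutoff_hz must be below the Nyquist frequency")
  if (sd < 0) abort("sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  if (sd == 0) return(constant_stimulus(mean, duration, dt, tau))
  z <- rnorm(n)
  bf <- signal::butter(filter_order, cutoff_hz / (fs / 2), type = "low")
  y <- as.numeric(signal::filter(bf, z))
  y <- (y - base::mean(y)) / stats::sd(y) * sd + mean
  as_stimulus(y, tau = tau, dt = dt)
}

#' Recover the command trace from a target trace
#'
#' Inverts the target dynamics `tau dx/dt = -x + c` by forward differences:
#' `c = tau * dx/dt + x`. The final sample is copied from its predecessor.
#' Integrating the dynamics forward (Euler) with the returned command
#' reproduces `x` exactly on the grid.
#'
#' @inheritParams as_stimulus
#' @return Numeric command trace, same length as `x`.
#' @export
command_from_target <- function(x, tau, dt) {
  if (length(x) < 2L) abort("need at least 2 samples to differentiate")
  cmd <- tau * diff(x) / dt + x[-length(x)]
  c(cmd, cmd[length(cmd)])
}

stimulus_dt <- function(stimulus) {
  attr(stimulus, "dt") %||% (stimulus$time[2] - stimulus$time[1])
}
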