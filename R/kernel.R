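#' Synaptic kernel specification
#'
#' Double-exponential postsynaptic current waveform with a transmission
#' delay:
#' \deqn{h(t) = \frac{e^{-(t-\tau_{tr})/\tau_d} - e^{-(t-\tau_{tr})/\tau_r}}
#'   {\tau_d - \tau_r} \quad (t > \tau_{tr}), \qquad h(t) = 0 \ (t \le \tau_{tr}).}
#' The `tau_decay - tau_rise` normalization makes the continuous-time
#' integral unity, so one presynaptic spike delivers a total mass equal to
#' the connection weight.
#'
#' @param tau_rise Synaptic rise time (s).
#' @param tau_decay Synaptic decay time (s); must exceed `tau_rise`.
#' @param delay Transmission delay (s).
#' @return An object of class `synapse_kernel`.
#' @examples
#' synapse_kernel()  # the default 1 ms / 3 ms / 1 ms waveform
#' @export
synapse_kernel <- function(tau_rise = 1e-3, tau_decay = 3e-3, delay = 1e-3) {
  if (tau_decay <= tau_rise) abort("tau_decay must exceed tau_rise (degenerate normalization)")
  if (tau_rise <= 0) abort("tau_rise must be positive")
  if (delay < 0) abort("delay must be non-negative")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, delay = delay),
            class = "synapse_kernel")
}

#' @export
print.synapse_kernel <- function(x, ...) {
  cat(sprintf("<synapse_kernel: rise %.3g ms, decay %.3g ms, delay %.3g ms>\n",
              x$tau_rise * 1e3, x$tau_decay * 1e3, x$delay * 1e3))
  invisible(x)
}

#' Sample a synaptic kernel on the simulation grid
#'
#' Evaluates the waveform on a grid of step `dt` (support truncated at
#' `10 * tau_decay + delay`) and renormalizes so that the discrete sum times
#' `dt` is exactly 1.
#'
#' @param kernel A [synapse_kernel()].
#' @param dt Grid step (s).
#' @return Tibble with columns `time` and `value`.
#' @export
sample_kernel <- function(kernel, dt) {
  stopifnot(inherits(kernel, "synapse_kernel"), dt > 0)
  t_max <- 10 * kernel$tau_decay + kernel$delay
  tt <- seq(0, t_max, by = dt)
  u <- tt - kernel$delay
  v <- ifelse(tt > kernel$delay,
              (exp(-u / kernel$tau_decay) - exp(-u / kernel$tau_rise)) /
                (kernel$tau_decay - kernel$tau_rise),
              0)
  v <- v / (sum(v) * dt)
  tibble(time = tt, value = v)
}

#' Effective synaptic delay
#'
#' The time for the cumulative input due to a single synaptic event to reach
#' half of its total mass, computed by numerical cumulative summation of the
#' sampled kernel. In the limit of zero rise time and zero transmission delay
#' this tends to `tau_decay * log(2)`.
#'
#' @param kernel A [synapse_kernel()].
#' @param dt Sampling step for the numerical cumulative sum (s).
#' @return Delay in seconds.
#' @export
effective_synaptic_delay <- function(kernel, dt = 1e-5) {
  k <- sample_kernel(kernel, dt)
  cum <- cumsum(k$value) * dt
  k$time[which(cum >= 0.5)[1]]
}
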