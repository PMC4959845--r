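#' Firing threshold of an efficient-coding neuron
#'
#' In the greedy efficient-coding rule, a neuron fires exactly when doing so
#' lowers the instantaneous coding loss. This reduces to comparing the
#' membrane voltage against the fixed threshold
#' \deqn{T = (w^2 + \alpha + \beta)/2,}
#' where `w` is the neuron's readout weight and `alpha`/`beta` the L1/L2
#' spike costs.
#'
#' @param w Readout weight(s).
#' @param l1_cost,l2_cost Non-negative L1 and L2 spike-cost parameters.
#' @return Threshold value(s), same length as `w`.
#' @examples
#' spike_threshold(1, 0, 0.04)   # 0.52
#' @export
spike_threshold <- function(w, l1_cost = 0, l2_cost = 0) {
  if (any(l1_cost < 0) || any(l2_cost < 0)) abort("spike costs must be non-negative")
  0.5 * (w^2 + l1_cost + l2_cost)
}

#' Membrane voltage implied by the coding state
#'
#' The membrane potential of an efficient-coding neuron equals a weighted
#' prediction error minus a rate-dependent hyperpolarization:
#' `V = w * (x - xhat) - l2_cost * r`.
#'
#' @param w Readout weight.
#' @param x Target value.
#' @param xhat Current readout (reconstruction) value.
#' @param l2_cost L2 spike cost.
#' @param r Filtered own-spike rate variable.
#' @return Voltage value(s).
#' @export
membrane_voltage <- function(w, x, xhat, l2_cost, r) {
  w * (x - xhat) - l2_cost * r
}

#' Instantaneous coding loss
#'
#' Squared reconstruction error plus L1 and L2 penalties on the per-neuron
#' rate variables: `(x - xhat)^2 + l1 * sum(r) + l2 * sum(r^2)`.
#'
#' @param x Target value.
#' @param xhat Readout value.
#' @param rates Non-negative per-neuron rate variables.
#' @param l1_cost,l2_cost Spike-cost parameters.
#' @return The scalar loss.
#' @export
coding_loss <- function(x, xhat, rates, l1_cost = 0, l2_cost = 0) {
  if (any(rates < 0)) abort("rates must be non-negative")
  (x - xhat)^2 + l1_cost * sum(rates) + l2_cost * sum(rates^2)
}

#' Configuration of the ideal (instantaneous-synapse) network
#'
#' @param n_neurons Number of neurons.
#' @param weights Readout weights; recycled to `n_neurons`.
#' @param l1_cost,l2_cost Spike costs.
#' @param tau Readout/membrane time constant (s).
#' @param noise_sd Voltage-noise scale; per Euler step each voltage receives
#'   `noise_sd * sqrt(dt/tau)` times a standard normal deviate.
#' @param dt Integration step (s); must be much smaller than `tau`.
#' @return An object of class `ideal_config`.
#' @examples
#' cfg <- ideal_config(3)  # the 3-neuron toy network
#' @export
ideal_config <- function(n_neurons, weights = 1, l1_cost = 0, l2_cost = 0.04,
                         tau = 0.1, noise_sd = 0.02, dt = 5e-4) {
  stopifnot(n_neurons >= 1, tau > 0, dt > 0, dt < tau / 10,
            l1_cost >= 0, l2_cost >= 0, noise_sd >= 0)
  weights <- rep_len(weights, n_neurons)
  structure(list(n_neurons = as.integer(n_neurons), weights = weights,
                 l1_cost = l1_cost, l2_cost = l2_cost, tau = tau,
                 noise_sd = noise_sd, dt = dt),
            class = "ideal_config")
}

#' Simulate the ideal efficient-coding network
#'
#' Forward-Euler integration of the leaky integrate-and-fire dynamics derived
#' from the coding loss, with instantaneous recurrence. At most one neuron
#' (the one with the highest supra-threshold voltage) fires per bin; exact
#' ties go to the lowest index. One spike of neuron `i` increments the
#' readout by `w_i`, its rate variable by 1, decrements every voltage by
#' `w_k * w_i` and the spiker's voltage by an additional `l2_cost` (reset).
#' With zero noise the integrated voltage equals the closed form
#' `w (x - xhat) - l2 r` at every recorded sample.
#'
#' @param config An [ideal_config()].
#' @param stimulus A stimulus tibble (see [as_stimulus()]); its grid step
#'   must equal `config$dt`.
#' @param seed Optional integer seed for the voltage noise.
#' @return A `sim_result` object; see [tidy.sim_result()] and
#'   [glance.sim_result()].
#' @export
simulate_ideal <- function(config, stimulus, seed = NULL) {
  stopifnot(inherits(config, "ideal_config"))
  dt <- stimulus_dt(stimulus)
  if (abs(dt - config$dt) > 1e-12) abort("stimulus grid step must equal config dt")
  if (!is.null(seed)) set.seed(seed)
  raw <- simulate_ideal_cpp(config$weights, config$l1_cost, config$l2_cost,
                            config$tau, config$noise_sd, config$dt, stimulus$c)
  spikes <- tibble(time = raw$spike_bin * dt,
                   neuron = as.integer(raw$spike_neuron),
                   population = "single")
  new_sim_result(
    variant = "ideal",
    spikes = spikes,
    readout = tibble(time = stimulus$time, xhat = raw$readout),
    voltage = list(single = raw$voltage),
    rate = raw$rate,
    inputs = NULL,
    stimulus = stimulus,
    config = config,
    seed = seed,
    dt = dt,
    duration = length(stimulus$time) * dt,
    n = c(single = config$n_neurons)
  )
}

new_sim_result <- function(...) {
  structure(list(...), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %s network, %d neurons, %.2f s at dt = %g s>\n",
              x$variant, sum(x$n), x$duration, x$dt))
  cat(sprintf("  spikes: %d (%.2f spikes/s/neuron overall)\n",
              nrow(x$spikes), nrow(x$spikes) / sum(x$n) / x$duration))
  invisible(x)
}

#' @rdname simulate_ideal
#' @param x,data,... Method arguments.
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) x$spikes

#' One-row summary of a simulation
#'
#' Reports per-population mean firing rates (spikes/s/neuron, after burn-in)
#' and spike counts.
#'
#' @param x A `sim_result`.
#' @param burn_in Initial interval (s) excluded from rates.
#' @param ... Unused.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, burn_in = 0.5, ...) {
  keep <- x$spikes$time > burn_in
  span <- x$duration - burn_in
  pops <- names(x$n)
  rates <- vapply(pops, function(p) {
    sum(keep & x$spikes$population == p) / x$n[[p]] / span
  }, numeric(1))
  out <- tibble(variant = x$variant, duration = x$duration,
                n_spikes = nrow(x$spikes))
  for (p in pops) out[[paste0("rate_", p)]] <- rates[[p]]
  out
}

#' Per-neuron mean firing rates
#'
#' @param result A `sim_result`.
#' @param burn_in Initial interval (s) excluded.
#' @return Tibble with columns `population`, `neuron`, `rate`.
#' @export
firing_rates <- function(result, burn_in = 0.5) {
  span <- result$duration - burn_in
  pops <- names(result$n)
  purrr::map_dfr(pops, function(p) {
    counts <- tabulate(result$spikes$neuron[result$spikes$population == p &
                                              result$spikes$time > burn_in],
                       nbins = result$n[[p]])
    tibble(population = p, neuron = seq_len(result$n[[p]]), rate = counts / span)
  })
}
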