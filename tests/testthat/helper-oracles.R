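# Independent oracles used across tests.

# Brute-force greedy decision: does spiking lower the instantaneous loss?
# A spike of neuron i adds w[i] to the readout and 1 to r[i].
greedy_loss_decision <- function(w, x, xhat, r, l1, l2, i) {
  r_spike <- r
  r_spike[i] <- r_spike[i] + 1
  coding_loss(x, xhat + w[i], r_spike, l1, l2) <
    coding_loss(x, xhat, r, l1, l2)
}

# Closed-form voltage w (x - xhat) - l2 * r recomputed from the spike raster
# with the same forward-Euler decay used by the simulator.
closed_form_voltage <- function(sim, x_trace) {
  cfg <- sim$config
  n <- length(x_trace)
  a <- cfg$dt / cfg$tau
  spk <- split(sim$spikes$neuron, as.integer(round(sim$spikes$time / cfg$dt)))
  v <- matrix(0, n, cfg$n_neurons)
  r <- numeric(cfg$n_neurons)
  xh <- 0
  for (t in seq_len(n)) {
    xh <- xh * (1 - a)
    r <- r * (1 - a)
    s <- spk[[as.character(t)]]
    if (!is.null(s)) {
      for (k in s) {
        xh <- xh + cfg$weights[k]
        r[k] <- r[k] + 1
      }
    }
    v[t, ] <- cfg$weights * (x_trace[t] - xh) - cfg$l2_cost * r
  }
  v
}

# Direct discrete convolution of a spike train with the double-exponential
# kernel, reproducing what the simulator's two-state filters compute.
direct_convolution_drive <- function(spikes_bin, spikes_neuron, weights_row,
                                     n_steps, dt, tau_r, tau_d, delay_bins) {
  qd <- exp(-dt / tau_d)
  qr <- exp(-dt / tau_r)
  mass <- 1 / (1 - qd) - 1 / (1 - qr)
  scale <- 1 / (dt * mass)
  g <- numeric(n_steps)
  for (j in seq_along(spikes_bin)) {
    first <- spikes_bin[j] + delay_bins
    if (first > n_steps) next
    m <- 0:(n_steps - first)
    g[first:n_steps] <- g[first:n_steps] +
      weights_row[spikes_neuron[j]] * (qd^m - qr^m) * scale
  }
  g
}

default_gamma_run <- function(seed, duration = 5.5, record_inputs = FALSE) {
  cfg <- ei_config()
  st <- constant_stimulus(50, duration = duration, dt = cfg$dt, tau = cfg$tau)
  simulate_ei(cfg, st, seed = seed, record_inputs = record_inputs)
}
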