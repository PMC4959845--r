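#' Configuration of the excitatory/inhibitory efficient-coding network
#'
#' The Dale's-law variant of the efficient-coding network: a population of
#' excitatory neurons encodes the target and a population of inhibitory
#' neurons tracks the excitatory reconstruction and supplies all recurrent
#' inhibition. Cross-neuron spike effects are transmitted through a
#' double-exponential synaptic waveform with a transmission delay (see
#' [synapse_kernel()]); own-spike resets are instantaneous.
#'
#' Defaults are the standard operating point of the model: 50 + 50 neurons,
#' readout weights 1.2 (mV^1/2 scale), L2 cost 8.5 mV, time constant 0.1 s,
#' voltage noise 17, kernel 1 ms rise / 3 ms decay / 1 ms delay, Euler step
#' 0.5 ms.
#'
#' @param n_exc,n_inh Population sizes.
#' @param w_exc,w_inh Readout weights (positive; recycled, or ignored when
#'   `connectivity` is `"heterogeneous"`/`"permuted"`, in which case weights
#'   are drawn from a gamma distribution with mean 1.2 and SD 0.5).
#' @param l1_exc,l2_exc,l1_inh,l2_inh Spike costs per population.
#' @param tau Readout/membrane time constant (s).
#' @param noise_sd Voltage-noise scale (per Euler step each voltage receives
#'   `noise_sd * sqrt(dt/tau)` times a standard normal deviate).
#' @param dt Euler step (s).
#' @param kernel A [synapse_kernel()].
#' @param fail_prob Per-(spike, target) Bernoulli transmission-failure
#'   probability; surviving recurrent weights are divided by `1 - fail_prob`
#'   so the expected delivered mass is unchanged.
#' @param poisson_fraction Fraction of cells in each population replaced by
#'   rate-matched Poisson emitters (rates measured from a reference run of
#'   the intact network).
#' @param connectivity One of `"homogeneous"`, `"heterogeneous"`,
#'   `"permuted"`. Connection matrices are outer products of readout weights
#'   ("precisely balanced"); in `"permuted"` mode each row of the E-to-I and
#'   I-to-E matrices is independently permuted (row sums, i.e. summed input
#'   per neuron, preserved) while I-to-I connections are left unchanged.
#' @return An object of class `ei_config`.
#' @examples
#' cfg <- ei_config()
#' @export
ei_config <- function(n_exc = 50, n_inh = 50, w_exc = 1.2, w_inh = 1.2,
                      l1_exc = 0, l2_exc = 8.5, l1_inh = 0, l2_inh = 8.5,
                      tau = 0.1, noise_sd = 17, dt = 5e-4,
                      kernel = synapse_kernel(),
                      fail_prob = 0, poisson_fraction = 0,
                      connectivity = c("homogeneous", "heterogeneous", "permuted")) {
  connectivity <- match.arg(connectivity)
  stopifnot(n_exc >= 1, n_inh >= 1, tau > 0, dt > 0, dt < tau / 10,
            l1_exc >= 0, l2_exc >= 0, l1_inh >= 0, l2_inh >= 0,
            noise_sd >= 0, fail_prob >= 0, fail_prob < 1,
            poisson_fraction >= 0, poisson_fraction <= 1)
  w_exc <- rep_len(w_exc, n_exc)
  w_inh <- rep_len(w_inh, n_inh)
  if (any(w_exc <= 0) || any(w_inh <= 0)) abort("all readout weights must be positive")
  stopifnot(inherits(kernel, "synapse_kernel"))
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 w_exc = w_exc, w_inh = w_inh,
                 l1_exc = l1_exc, l2_exc = l2_exc,
                 l1_inh = l1_inh, l2_inh = l2_inh,
                 tau = tau, noise_sd = noise_sd, dt = dt, kernel = kernel,
                 fail_prob = fail_prob, poisson_fraction = poisson_fraction,
                 connectivity = connectivity),
            class = "ei_config")
}

#' @export
print.ei_config <- function(x, ...) {
  cat(sprintf(paste0("<ei_config: %d E + %d I, tau %.3g s, noise %.3g, ",
                     "L2 (E/I) %.3g/%.3g, %s connectivity>\n"),
              x$n_exc, x$n_inh, x$tau, x$noise_sd, x$l2_exc, x$l2_inh,
              x$connectivity))
  invisible(x)
}

#' Build the connectivity of an E/I network
#'
#' Connection matrices are outer products of readout weights: entry `(i, k)`
#' of the I-to-E matrix is `w_exc[i] * w_inh[k]`, and analogously for E-to-I
#' and I-to-I. There is no E-to-E connection. In `"heterogeneous"` mode the
#' readout weights are drawn from a gamma distribution with mean 1.2 and SD
#' 0.5 (precisely balanced); `"permuted"` mode additionally permutes each row
#' of the E-to-I and I-to-E matrices independently, preserving every
#' neuron's summed input but breaking the reciprocal symmetry. Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param config An [ei_config()].
#' @return List with weight vectors `w_exc`, `w_inh` and matrices `w_ie`
#'   (I to E, `n_exc` x `n_inh`), `w_ei` (E to I, `n_inh` x `n_exc`),
#'   `w_ii` (I to I).
#' @export
build_connectivity <- function(config) {
  stopifnot(inherits(config, "ei_config"))
  w_exc <- config$w_exc
  w_inh <- config$w_inh
  if (config$connectivity %in% c("heterogeneous", "permuted")) {
    m <- 1.2; s <- 0.5
    shape <- (m / s)^2
    w_exc <- stats::rgamma(config$n_exc, shape = shape, rate = m / s^2)
    w_inh <- stats::rgamma(config$n_inh, shape = shape, rate = m / s^2)
  }
  w_ie <- outer(w_exc, w_inh)   # I -> E input weights
  w_ei <- outer(w_inh, w_exc)   # E -> I input weights
  w_ii <- outer(w_inh, w_inh)   # I -> I input weights
  if (config$connectivity == "permuted") {
    w_ie <- t(apply(w_ie, 1, sample))
    w_ei <- t(apply(w_ei, 1, sample))
    # recurrent inhibitory (I -> I) connections left unchanged
  }
  list(w_exc = w_exc, w_inh = w_inh, w_ie = w_ie, w_ei = w_ei, w_ii = w_ii,
       mode = config$connectivity)
}

#' Simulate the delayed-synapse E/I network
#'
#' Forward-Euler integration of the excitatory/inhibitory efficient-coding
#' network. Excitatory neurons receive feed-forward drive `w c(t)` and
#' delayed, kernel-filtered inhibition; inhibitory neurons receive delayed
#' excitation from the E population and delayed recurrent inhibition. Any
#' number of neurons may fire in a bin. Both populations' readouts
#' (excitatory and inhibitory reconstructions) are decoded on the fly.
#'
#' @param config An [ei_config()].
#' @param stimulus A stimulus tibble; grid step must equal `config$dt`.
#' @param seed Integer seed controlling noise, connectivity draws, failures
#'   and Poisson substitution.
#' @param record_voltage,record_inputs Record per-neuron voltage traces and
#'   separated excitatory/inhibitory synaptic input traces (mV/s).
#' @param connectivity Optional pre-built [build_connectivity()] result
#'   (e.g. to hold connectivity fixed across calibration chunks).
#' @param reference_rates Optional list with per-neuron rates `exc`, `inh`
#'   used for Poisson-substituted cells; measured from a reference run of
#'   the intact network when `NULL`.
#' @return A `sim_result` with populations `"exc"` and `"inh"`, readouts for
#'   both, and (optionally) voltage and input traces.
#' @export
simulate_ei <- function(config, stimulus, seed = 1L,
                        record_voltage = TRUE, record_inputs = FALSE,
                        connectivity = NULL, reference_rates = NULL) {
  stopifnot(inherits(config, "ei_config"))
  dt <- stimulus_dt(stimulus)
  if (abs(dt - config$dt) > 1e-12) abort("stimulus grid step must equal config dt")
  set.seed(seed)
  conn <- connectivity %||% build_connectivity(config)

  pois_e <- rep(FALSE, config$n_exc)
  pois_i <- rep(FALSE, config$n_inh)
  rate_e <- rate_i <- NULL
  if (config$poisson_fraction > 0) {
    k_e <- round(config$poisson_fraction * config$n_exc)
    k_i <- round(config$poisson_fraction * config$n_inh)
    if (k_e > 0) pois_e[sample(config$n_exc, k_e)] <- TRUE
    if (k_i > 0) pois_i[sample(config$n_inh, k_i)] <- TRUE
    if (is.null(reference_rates)) {
      cfg0 <- config
      cfg0$poisson_fraction <- 0
      ref <- simulate_ei(cfg0, stimulus, seed = (seed %% 100000L) + 10007L,
                         record_voltage = FALSE, connectivity = conn)
      rr <- firing_rates(ref)
      reference_rates <- list(exc = rr$rate[rr$population == "exc"],
                              inh = rr$rate[rr$population == "inh"])
      set.seed(seed)
      conn2 <- build_connectivity(config)   # replay draws to realign the stream
      if (k_e > 0) pois_e <- replace(rep(FALSE, config$n_exc), sample(config$n_exc, k_e), TRUE)
      if (k_i > 0) pois_i <- replace(rep(FALSE, config$n_inh), sample(config$n_inh, k_i), TRUE)
    }
    rate_e <- reference_rates$exc
    rate_i <- reference_rates$inh
  }
  if (is.null(rate_e)) rate_e <- numeric(config$n_exc)
  if (is.null(rate_i)) rate_i <- numeric(config$n_inh)

  delay_bins <- as.integer(round(config$kernel$delay / dt))
  raw <- simulate_ei_cpp(conn$w_exc, conn$w_inh,
                         config$l1_exc, config$l2_exc,
                         config$l1_inh, config$l2_inh,
                         config$tau, config$noise_sd, dt, stimulus$c,
                         conn$w_ie, conn$w_ei, conn$w_ii,
                         config$kernel$tau_rise, config$kernel$tau_decay,
                         delay_bins, config$fail_prob,
                         pois_e, pois_i, rate_e, rate_i,
                         record_voltage, record_inputs)

  spikes <- dplyr::bind_rows(
    tibble(time = raw$spike_bin_e * dt, neuron = as.integer(raw$spike_neuron_e),
           population = "exc"),
    tibble(time = raw$spike_bin_i * dt, neuron = as.integer(raw$spike_neuron_i),
           population = "inh")
  ) %>% arrange(.data$time)

  new_sim_result(
    variant = "ei",
    spikes = spikes,
    readout = tibble(time = stimulus$time, xhat_e = raw$readout_e,
                     xhat_i = raw$readout_i),
    voltage = if (record_voltage) list(exc = raw$voltage_e, inh = raw$voltage_i),
    inputs = if (record_inputs) list(exc_on_exc = raw$exc_input_e,
                                     inh_on_exc = raw$inh_input_e,
                                     exc_on_inh = raw$exc_input_i,
                                     inh_on_inh = raw$inh_input_i),
    rate = NULL,
    stimulus = stimulus,
    config = config,
    connectivity = conn,
    poisson_cells = list(exc = which(pois_e), inh = which(pois_i)),
    seed = seed,
    dt = dt,
    duration = length(stimulus$time) * dt,
    n = c(exc = config$n_exc, inh = config$n_inh)
  )
}

#' Read / write an E/I network configuration as YAML
#'
#' The file uses flat field names (`n_e`, `n_i`, `gamma0_mV12`, `beta_mV`,
#' `sigma`, `tau_s`, `tau_r_ms`, `tau_d_ms`, `tau_tr_ms`, `dt_ms`,
#' `failure_prob`, `poisson_fraction`, `connectivity_mode`, `seed`).
#'
#' @param path File path.
#' @return For `read_ei_config()`, a list with elements `config` (an
#'   [ei_config()]) and `seed`.
#' @export
read_ei_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(nm, default) y[[nm]] %||% default
  cfg <- ei_config(
    n_exc = g("n_e", 50), n_inh = g("n_i", 50),
    w_exc = g("gamma0_mV12", 1.2), w_inh = g("gamma0_mV12", 1.2),
    l2_exc = g("beta_mV", 8.5), l2_inh = g("beta_mV", 8.5),
    noise_sd = g("sigma", 17), tau = g("tau_s", 0.1),
    dt = g("dt_ms", 0.5) / 1e3,
    kernel = synapse_kernel(g("tau_r_ms", 1) / 1e3, g("tau_d_ms", 3) / 1e3,
                            g("tau_tr_ms", 1) / 1e3),
    fail_prob = g("failure_prob", 0),
    poisson_fraction = g("poisson_fraction", 0),
    connectivity = g("connectivity_mode", "homogeneous")
  )
  list(config = cfg, seed = as.integer(g("seed", 1)))
}

#' @rdname read_ei_config
#' @param config An [ei_config()].
#' @param seed Integer seed stored alongside the parameters.
#' @export
write_ei_config <- function(config, path, seed = 1L) {
  stopifnot(inherits(config, "ei_config"))
  y <- list(n_e = config$n_exc, n_i = config$n_inh,
            gamma0_mV12 = config$w_exc[1], beta_mV = config$l2_exc,
            sigma = config$noise_sd, tau_s = config$tau,
            tau_r_ms = config$kernel$tau_rise * 1e3,
            tau_d_ms = config$kernel$tau_decay * 1e3,
            tau_tr_ms = config$kernel$delay * 1e3,
            dt_ms = config$dt * 1e3,
            failure_prob = config$fail_prob,
            poisson_fraction = config$poisson_fraction,
            connectivity_mode = config$connectivity,
            seed = seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
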