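#' Sweep specification
#'
#' Describes one of the scripted experiments: which parameter is varied,
#' over which grid, with how many seeds and how much simulated time per
#' point.
#'
#' @param experiment One of `"noise_sweep"`, `"failure_sweep"`,
#'   `"poisson_fraction_sweep"`, `"amplitude_set"`, `"size_sweep"`,
#'   `"inhibitory_size_sweep"`, `"delay_sweep"`, `"tau_sweep"`,
#'   `"heterogeneous_vs_permuted"`.
#' @param grid Values of the swept parameter (non-empty). For
#'   `heterogeneous_vs_permuted` a character vector of connectivity modes;
#'   for `delay_sweep` multiplicative scale factors on all three kernel time
#'   constants.
#' @param seeds Integer seeds (at least one); metrics can then be averaged
#'   over seeds.
#' @param duration Simulated time per grid point (s), including `burn_in`.
#' @param amplitude Constant target amplitude.
#' @param calibrate Run the bias-nulling calibration at each grid point
#'   before the measurement run. Defaults to `TRUE` for the sweeps that
#'   change synchrony or rates (noise, failures, Poisson fraction, sizes,
#'   time constants) and `FALSE` otherwise.
#' @param burn_in Transient excluded from all metrics (s).
#' @param poisson_reference Also compute the rate-matched independent-Poisson
#'   baseline error at each point.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(experiment = c("noise_sweep", "failure_sweep",
                                      "poisson_fraction_sweep", "amplitude_set",
                                      "size_sweep", "inhibitory_size_sweep",
                                      "delay_sweep", "tau_sweep",
                                      "heterogeneous_vs_permuted"),
                       grid, seeds = 1:3, duration = 10, amplitude = 50,
                       calibrate = NULL, burn_in = 0.5,
                       poisson_reference = FALSE) {
  experiment <- match.arg(experiment)
  if (length(grid) == 0) abort("grid must be non-empty")
  if (length(seeds) == 0) abort("at least one seed is required")
  if (is.null(calibrate)) {
    calibrate <- experiment %in% c("noise_sweep", "failure_sweep",
                                   "poisson_fraction_sweep", "size_sweep",
                                   "inhibitory_size_sweep", "delay_sweep",
                                   "tau_sweep")
  }
  structure(list(experiment = experiment, grid = grid,
                 seeds = as.integer(seeds), duration = duration,
                 amplitude = amplitude, calibrate = calibrate,
                 burn_in = burn_in, poisson_reference = poisson_reference),
            class = "sweep_spec")
}

apply_sweep_point <- function(config, experiment, value) {
  switch(experiment,
    noise_sweep = { config$noise_sd <- value; config },
    failure_sweep = { config$fail_prob <- value; config },
    poisson_fraction_sweep = { config$poisson_fraction <- value; config },
    amplitude_set = config,
    size_sweep = ei_config(
      n_exc = value, n_inh = value, w_exc = config$w_exc[1],
      w_inh = config$w_inh[1], l1_exc = config$l1_exc, l2_exc = config$l2_exc,
      l1_inh = config$l1_inh, l2_inh = config$l2_inh, tau = config$tau,
      noise_sd = config$noise_sd, dt = config$dt, kernel = config$kernel,
      fail_prob = config$fail_prob, poisson_fraction = config$poisson_fraction,
      connectivity = config$connectivity),
    inhibitory_size_sweep = ei_config(
      n_exc = config$n_exc, n_inh = value, w_exc = config$w_exc[1],
      w_inh = config$w_inh[1], l1_exc = config$l1_exc, l2_exc = config$l2_exc,
      l1_inh = config$l1_inh, l2_inh = config$l2_inh, tau = config$tau,
      noise_sd = config$noise_sd, dt = config$dt, kernel = config$kernel,
      fail_prob = config$fail_prob, poisson_fraction = config$poisson_fraction,
      connectivity = config$connectivity),
    delay_sweep = {
      k <- config$kernel
      config$kernel <- synapse_kernel(k$tau_rise * value, k$tau_decay * value,
                                      k$delay * value)
      config
    },
    tau_sweep = { config$tau <- value; config },
    heterogeneous_vs_permuted = { config$connectivity <- value; config },
    abort(sprintf("unknown experiment '%s'", experiment))
  )
}

#' Run a parameter sweep
#'
#' For each grid point and seed: optionally calibrate the spike costs (bias
#' nulling at the sweep amplitude), simulate, and compute the standard
#' metric set — mean-normalized reconstruction error, E/I reconstruction
#' mismatch, estimation bias, per-cell spiking CV, mean pairwise voltage
#' correlation (excitatory cells), per-neuron mean firing rates, and the
#' multitaper peak frequency of the excitatory population rate. Failures at
#' individual points are recorded (`error_message` column) and the sweep
#' continues. Deterministic given `spec$seeds`.
#'
#' @param spec A [sweep_spec()].
#' @param base_config An [ei_config()] modified at each grid point.
#' @return A tibble with one row per (grid value, seed).
#' @export
run_sweep <- function(spec, base_config = ei_config()) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(base_config, "ei_config"))
  grid <- spec$grid
  rows <- purrr::map(seq_along(grid), function(gi) {
    purrr::map(spec$seeds, function(sd) {
      res <- tryCatch(
        run_sweep_point(spec, base_config, grid[gi], sd),
        error = function(e) tibble(error_message = conditionMessage(e))
      )
      dplyr::bind_cols(tibble(value = grid[gi], seed = sd), res)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

run_sweep_point <- function(spec, base_config, value, seed) {
  config <- apply_sweep_point(base_config, spec$experiment, value)
  amplitude <- if (spec$experiment == "amplitude_set") value else spec$amplitude
  stim <- constant_stimulus(amplitude, duration = spec$duration,
                            dt = config$dt, tau = config$tau)
  if (spec$calibrate) {
    cal <- calibrate_costs(config, seed = seed,
                           stimulus = constant_stimulus(
                             amplitude, duration = 2.5, dt = config$dt,
                             tau = config$tau))
    config <- cal$config
  }
  sim <- simulate_ei(config, stim, seed = seed, record_voltage = TRUE)
  x <- stim$x
  xe <- sim$readout$xhat_e
  xi <- sim$readout$xhat_i
  keep <- stim$time > spec$burn_in
  rates <- firing_rates(sim, spec$burn_in)
  rate_e <- mean(rates$rate[rates$population == "exc"])
  rate_i <- mean(rates$rate[rates$population == "inh"])
  cv <- isi_statistics(sim$spikes, "per_cell", population = "exc")$cv
  vstats <- voltage_pair_statistics(
    sim$voltage$exc[keep, seq_len(min(20, config$n_exc)), drop = FALSE],
    fs = 1 / config$dt)
  pr <- population_rate(sim$spikes, config$n_exc, sim$duration, config$dt,
                        population = "exc")
  spec_e <- power_spectrum(pr$rate[keep], fs = 1 / config$dt)
  out <- tibble(
    error = reconstruction_error(x, xe, config$dt, spec$burn_in, "mean"),
    ei_mismatch = sqrt(mean((xe[keep] - xi[keep])^2)),
    bias = estimation_bias(x, xe, config$dt, spec$burn_in),
    cv = cv,
    voltage_correlation = vstats$correlation,
    rate_exc = rate_e, rate_inh = rate_i,
    peak_frequency = peak_frequency(spec_e),
    l2_exc = config$l2_exc, l2_inh = config$l2_inh,
    calibrated = spec$calibrate
  )
  if (spec$poisson_reference) {
    pois <- simulate_poisson_baseline(
      rates$rate[rates$population == "exc"], sim$connectivity$w_exc,
      config$tau, spec$duration, config$dt, seed = seed + 500000L)
    out$poisson_error <- reconstruction_error(x, pois$readout$xhat, config$dt,
                                              spec$burn_in, "mean")
  }
  out
}

#' Synchrony toy experiment
#'
#' Regular spike schedules encoding a constant: the population fires at
#' evenly spaced times, with groups of `k` neurons firing together at each
#' event (total spike rate held fixed), so `k = 1` is the perfectly
#' staggered code and `k = n_neurons` the fully synchronous one. Each
#' schedule is decoded with the leaky readout and scored by the
#' mean-normalized rms error against the encoded constant
#' `weight * total_rate * tau`. A matched-rate independent-Poisson
#' population provides the reference error.
#'
#' @param n_neurons Population size.
#' @param synchrony_k Numbers of synchronous spikes per event; each must
#'   divide `n_neurons` and not exceed it.
#' @param total_rate Total population spike rate (spikes/s).
#' @param tau Readout time constant (s).
#' @param duration Schedule duration (s).
#' @param dt Grid step (s).
#' @param weight Common readout weight.
#' @param burn_in Interval excluded from the error (s).
#' @param seed Seed for the Poisson reference.
#' @return Tibble with columns `k`, `error`, and the constant
#'   `poisson_error` reference.
#' @export
toy_synchrony_experiment <- function(n_neurons = 10, synchrony_k = c(1, 2, 5, 10),
                                     total_rate = 200, tau = 0.1, duration = 20,
                                     dt = 5e-4, weight = 1, burn_in = 1,
                                     seed = 1L) {
  if (any(synchrony_k > n_neurons)) abort("k cannot exceed n_neurons")
  if (any(n_neurons %% synchrony_k != 0)) abort("each k must divide n_neurons")
  target <- weight * total_rate * tau
  n_steps <- round(duration / dt)
  errors <- vapply(synchrony_k, function(k) {
    interval <- k / total_rate
    event_times <- seq(interval, duration, by = interval)
    neurons <- (((seq_along(event_times) - 1) * k) %% n_neurons)
    spikes <- tibble(
      time = rep(event_times, each = k),
      neuron = as.integer(1 + (rep(neurons, each = k) + 0:(k - 1)) %% n_neurons)
    )
    ro <- decode(spikes, rep(weight, n_neurons), tau, dt, n_steps)
    reconstruction_error(rep(target, n_steps), ro$xhat, dt, burn_in, "mean")
  }, numeric(1))
  pois <- simulate_poisson_baseline(rep(total_rate / n_neurons, n_neurons),
                                    weight, tau, duration, dt, seed = seed)
  pois_err <- reconstruction_error(rep(target, n_steps), pois$readout$xhat,
                                   dt, burn_in, "mean")
  tibble(k = synchrony_k, error = errors, poisson_error = pois_err)
}

#' Two-interval discrimination across noise levels
#'
#' For each noise level: calibrate the costs at the centre amplitude,
#' simulate long runs at the two amplitudes `centre +/- separation/2`,
#' carve the post-burn-in readout into 0.1 s segments (one per trial),
#' time-average the excitatory readout per segment, and apply
#' [discrimination_performance()].
#'
#' @param base_config An [ei_config()].
#' @param centre Centre amplitude.
#' @param separation Amplitude difference between the two stimuli.
#' @param noise_levels Noise scales to test.
#' @param trials Trials (0.1 s segments) per stimulus (at least 20).
#' @param segment_duration Trial segment length (s).
#' @param burn_in Transient excluded before segmenting (s).
#' @param seed Integer seed.
#' @param calibrate Calibrate costs per noise level.
#' @return Tibble with columns `noise_sd`, `d_prime`, `p_correct`.
#' @export
run_discrimination <- function(base_config = ei_config(), centre = 48,
                               separation = 4, noise_levels = 17, trials = 50,
                               segment_duration = 0.1, burn_in = 0.5,
                               seed = 1L, calibrate = TRUE) {
  if (trials < 20) abort("at least 20 trials are required")
  seg_bins <- round(segment_duration / base_config$dt)
  purrr::map_dfr(noise_levels, function(ns) {
    config <- base_config
    config$noise_sd <- ns
    if (calibrate) {
      cal <- calibrate_costs(config, seed = seed,
                             stimulus = constant_stimulus(
                               centre, duration = 2.5, dt = config$dt,
                               tau = config$tau))
      config <- cal$config
    }
    amplitudes <- centre + c(-0.5, 0.5) * separation
    dur <- burn_in + trials * segment_duration
    samples <- purrr::map(seq_along(amplitudes), function(ai) {
      stim <- constant_stimulus(amplitudes[ai], duration = dur,
                                dt = config$dt, tau = config$tau)
      sim <- simulate_ei(config, stim, seed = seed + ai,
                         record_voltage = FALSE)
      xe <- sim$readout$xhat_e[stim$time > burn_in]
      xe <- xe[seq_len(trials * seg_bins)]
      colMeans(matrix(xe, nrow = seg_bins))
    })
    perf <- discrimination_performance(samples[[1]], samples[[2]])
    tibble(noise_sd = ns, d_prime = perf$d_prime, p_correct = perf$p_correct)
  })
}
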