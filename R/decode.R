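#' Decode a spike raster into a continuous reconstruction
#'
#' Leaky integration of weighted spike trains: the readout starts at zero,
#' decays between spikes with time constant `tau` (forward-Euler decay
#' `1 - dt/tau` per bin, matching the simulators), and jumps by `weights[i]`
#' at each spike of neuron `i`.
#'
#' @param spikes Tibble with columns `time` and `neuron` (and optionally
#'   `population`), aligned to the grid.
#' @param weights Per-neuron readout weights.
#' @param tau Readout time constant (s).
#' @param dt Grid step (s).
#' @param n_steps Number of grid samples of the output.
#' @param population If given, only spikes of this population are decoded.
#' @return Tibble with columns `time` and `xhat`.
#' @export
decode <- function(spikes, weights, tau, dt, n_steps, population = NULL) {
  if (!is.null(population) && "population" %in% names(spikes)) {
    spikes <- spikes[spikes$population == population, , drop = FALSE]
  }
  if (nrow(spikes) > 0 && max(spikes$neuron) > length(weights)) {
    abort("weight vector shorter than the largest neuron index")
  }
  bins <- as.integer(round(spikes$time / dt))
  bins <- pmin(pmax(bins, 1L), n_steps)
  impulses <- numeric(n_steps)
  if (length(bins) > 0) {
    w <- weights[spikes$neuron]
    for (j in seq_along(bins)) impulses[bins[j]] <- impulses[bins[j]] + w[j]
  }
  xhat <- as.numeric(stats::filter(impulses, 1 - dt / tau, method = "recursive"))
  tibble(time = seq_len(n_steps) * dt, xhat = xhat)
}

#' Reconstruction error
#'
#' Root-mean-square difference between target and reconstruction over the
#' post-burn-in samples, normalized either by the standard deviation of the
#' target (`"variance"` mode, for time-varying targets) or by its mean
#' (`"mean"` mode, for constant targets).
#'
#' @param x Target trace.
#' @param xhat Reconstruction trace (same grid).
#' @param dt Grid step (s).
#' @param burn_in Initial interval (s) excluded.
#' @param mode Normalization mode.
#' @return The normalized error (non-negative scalar).
#' @export
reconstruction_error <- function(x, xhat, dt, burn_in = 0.5,
                                 mode = c("variance", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(xhat))
  keep <- seq_along(x) * dt > burn_in
  rms <- sqrt(mean((x[keep] - xhat[keep])^2))
  denom <- if (mode == "variance") sd(x[keep]) else mean(x[keep])
  if (!is.finite(denom) || denom == 0) {
    abort(sprintf("zero normalizer in '%s' mode (constant or zero-mean target)", mode))
  }
  rms / denom
}

#' Estimation bias
#'
#' Time-average of `xhat - x` over the post-burn-in samples.
#'
#' @inheritParams reconstruction_error
#' @return The signed bias.
#' @export
estimation_bias <- function(x, xhat, dt, burn_in = 0.5) {
  stopifnot(length(x) == length(xhat))
  keep <- seq_along(x) * dt > burn_in
  mean(xhat[keep] - x[keep])
}

#' Independent-Poisson rate-model baseline
#'
#' Each neuron fires an independent Poisson train at its given mean rate
#' (Bernoulli per bin with probability `rate * dt`); spikes are decoded with
#' the same leaky readout as the recurrent network.
#'
#' @param mean_rates Per-neuron firing rates (spikes/s).
#' @param weights Per-neuron readout weights.
#' @param tau Readout time constant (s).
#' @param duration Duration (s).
#' @param dt Grid step (s).
#' @param seed Optional integer seed.
#' @return A `sim_result` (variant `"poisson"`) with spikes and readout.
#' @export
simulate_poisson_baseline <- function(mean_rates, weights, tau, duration,
                                      dt = 5e-4, seed = NULL) {
  if (any(mean_rates < 0)) abort("rates must be non-negative")
  n <- length(mean_rates)
  weights <- rep_len(weights, n)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  fired <- matrix(runif(n_steps * n) < rep(mean_rates * dt, each = n_steps),
                  nrow = n_steps)
  idx <- which(fired, arr.ind = TRUE)
  spikes <- tibble(time = idx[, 1] * dt, neuron = as.integer(idx[, 2]),
                   population = "single") %>% arrange(.data$time)
  ro <- decode(spikes, weights, tau, dt, n_steps)
  new_sim_result(variant = "poisson", spikes = spikes,
                 readout = tibble(time = ro$time, xhat = ro$xhat),
                 voltage = NULL, inputs = NULL, rate = NULL,
                 stimulus = NULL, config = list(mean_rates = mean_rates,
                                                weights = weights, tau = tau),
                 seed = seed, dt = dt, duration = duration,
                 n = c(single = n))
}

#' Two-alternative discrimination performance
#'
#' Signal-detection summary for discriminating two stimuli from per-trial
#' readout estimates: the sensitivity
#' `d = (mean2 - mean1) / sqrt((var1 + var2)/2)` and the ideal-observer
#' probability of a correct choice `p = Phi(d / sqrt(2))`.
#'
#' @param estimates_1,estimates_2 Per-trial estimate samples under the two
#'   stimuli (at least 2 each).
#' @return Tibble with columns `d_prime` and `p_correct`.
#' @export
discrimination_performance <- function(estimates_1, estimates_2) {
  if (length(estimates_1) < 2 || length(estimates_2) < 2) {
    abort("need at least 2 samples per condition")
  }
  pooled <- 0.5 * (var(estimates_1) + var(estimates_2))
  if (pooled == 0) abort("zero pooled variance")
  d <- (mean(estimates_2) - mean(estimates_1)) / sqrt(pooled)
  tibble(d_prime = d, p_correct = pnorm(d / sqrt(2)))
}
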