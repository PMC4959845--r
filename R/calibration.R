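#' Bias-nulling calibration of the L2 spike costs
#'
#' Changing the voltage noise (or synaptic reliability) changes firing rates
#' and hence introduces systematic estimation biases. This routine adapts
#' the excitatory and inhibitory L2 costs online, in the spirit of a
#' stochastic-gradient scheme, until both biases vanish: after each
#' simulation chunk, `l2_exc <- l2_exc + learning_rate * bias_exc` and
#' `l2_inh <- l2_inh + learning_rate * bias_inh`, where `bias_exc` is the
#' mean of `xhat_e - x` and `bias_inh` the mean of `xhat_i - xhat_e` (the
#' inhibitory reconstruction targets the excitatory one). A positive bias
#' means over-estimation, so raising the cost lowers rates. The spike
#' threshold co-varies with the cost automatically, which is what holds
#' firing rates constant across noise levels.
#'
#' @param config An [ei_config()].
#' @param stimulus Constant-target stimulus used for each chunk; defaults to
#'   a constant 50 held for `burn_in + chunk_duration`.
#' @param learning_rate Cost increment per unit bias per chunk.
#' @param tolerance Absolute bias (same units as the target) below which
#'   calibration stops.
#' @param chunk_duration Post-burn-in length of each chunk (s).
#' @param burn_in Transient excluded from the bias estimate (s).
#' @param max_chunks Chunk budget; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @param seed Integer seed; chunk `k` uses `seed + k` so the procedure is
#'   deterministic. Connectivity is drawn once from `seed` and held fixed.
#' @return A `calibration_result`: list with the calibrated `config`,
#'   `l2_exc`, `l2_inh`, final `bias_exc`/`bias_inh`, `chunks_used`,
#'   `converged`, and a per-chunk `history` tibble.
#' @export
calibrate_costs <- function(config, stimulus = NULL, learning_rate = 0.5,
                            tolerance = 0.5, chunk_duration = 2,
                            burn_in = 0.5, max_chunks = 50, seed = 1L) {
  stopifnot(inherits(config, "ei_config"))
  if (is.null(stimulus)) {
    stimulus <- constant_stimulus(50, duration = burn_in + chunk_duration,
                                  dt = config$dt, tau = config$tau)
  }
  set.seed(seed)
  conn <- build_connectivity(config)
  history <- vector("list", max_chunks)
  converged <- FALSE
  bias_e <- bias_i <- NA_real_
  chunk <- 0L
  while (chunk < max_chunks) {
    chunk <- chunk + 1L
    sim <- simulate_ei(config, stimulus, seed = seed + chunk,
                       record_voltage = FALSE, connectivity = conn)
    bias_e <- estimation_bias(stimulus$x, sim$readout$xhat_e, config$dt, burn_in)
    bias_i <- estimation_bias(sim$readout$xhat_e, sim$readout$xhat_i,
                              config$dt, burn_in)
    history[[chunk]] <- tibble(chunk = chunk, l2_exc = config$l2_exc,
                               l2_inh = config$l2_inh,
                               bias_exc = bias_e, bias_inh = bias_i)
    if (abs(bias_e) < tolerance && abs(bias_i) < tolerance) {
      converged <- TRUE
      break
    }
    config$l2_exc <- max(config$l2_exc + learning_rate * bias_e, 1e-3)
    config$l2_inh <- max(config$l2_inh + learning_rate * bias_i, 1e-3)
  }
  structure(list(config = config, l2_exc = config$l2_exc,
                 l2_inh = config$l2_inh, bias_exc = bias_e, bias_inh = bias_i,
                 chunks_used = chunk, converged = converged,
                 history = dplyr::bind_rows(history)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %s in %d chunks; l2 (E/I) = %.3g/%.3g; bias (E/I) = %.3g/%.3g>\n",
              if (x$converged) "converged" else "NOT converged",
              x$chunks_used, x$l2_exc, x$l2_inh, x$bias_exc, x$bias_inh))
  invisible(x)
}

#' @rdname calibrate_costs
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$history

#' @rdname calibrate_costs
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble(l2_exc = x$l2_exc, l2_inh = x$l2_inh, bias_exc = x$bias_exc,
         bias_inh = x$bias_inh, chunks_used = x$chunks_used,
         converged = x$converged)
}
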