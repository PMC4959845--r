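#' Inter-spike-interval statistics
#'
#' ISIs are computed either from the pooled population spike train
#' (`scope = "pooled"`) or per cell (`scope = "per_cell"`). The coefficient
#' of variation (CV = SD/mean of the ISIs) is 0 for a perfectly regular
#' train and 1 for a Poisson train. In per-cell scope the CV is averaged
#' over cells with at least two ISIs.
#'
#' @param spikes Tibble with columns `time`, `neuron` (and optionally
#'   `population`).
#' @param scope `"pooled"` or `"per_cell"`.
#' @param population If given, restrict to this population first.
#' @return List with elements `scope`, `isi` (tibble of intervals), `cv`
#'   (NA if fewer than 2 intervals are available anywhere).
#' @export
isi_statistics <- function(spikes, scope = c("pooled", "per_cell"),
                           population = NULL) {
  scope <- match.arg(scope)
  if (!is.null(population) && "population" %in% names(spikes)) {
    spikes <- spikes[spikes$population == population, , drop = FALSE]
  }
  if (scope == "pooled") {
    tt <- sort(spikes$time)
    isi <- diff(tt)
    cv <- if (length(isi) >= 2) sd(isi) / mean(isi) else NA_real_
    return(list(scope = scope, isi = tibble(interval = isi), cv = cv))
  }
  per <- spikes %>%
    group_by(.data$neuron) %>%
    summarise(intervals = list(diff(sort(.data$time))), .groups = "drop")
  isi <- tibble(neuron = rep(per$neuron, lengths(per$intervals)),
                interval = unlist(per$intervals))
  cvs <- vapply(per$intervals, function(v) {
    if (length(v) >= 2) sd(v) / mean(v) else NA_real_
  }, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  list(scope = scope, isi = isi,
       cv = if (length(cvs) > 0) mean(cvs) else NA_real_)
}

#' Population firing rate trace
#'
#' Bins all spikes on the grid, converts to an instantaneous rate in
#' spikes/s/neuron, and optionally low-pass filters with a causal
#' first-order Butterworth filter (unit DC gain, so the time-mean of the
#' trace matches the overall mean rate up to edge effects).
#'
#' @param spikes Spike tibble (`time`, `neuron`).
#' @param n_neurons Number of neurons in the population.
#' @param duration Duration (s).
#' @param dt Grid step (s).
#' @param cutoff_hz Low-pass cut-off; `NULL` for the raw binned rate.
#' @param population Optional population filter.
#' @return Tibble with columns `time` and `rate`.
#' @export
population_rate <- function(spikes, n_neurons, duration, dt,
                            cutoff_hz = NULL, population = NULL) {
  if (!is.null(population) && "population" %in% names(spikes)) {
    spikes <- spikes[spikes$population == population, , drop = FALSE]
  }
  n_steps <- round(duration / dt)
  bins <- pmin(pmax(as.integer(round(spikes$time / dt)), 1L), n_steps)
  rate <- tabulate(bins, nbins = n_steps) / (n_neurons * dt)
  if (!is.null(cutoff_hz)) {
    fs <- 1 / dt
    if (cutoff_hz >= fs / 2) abort("cutoff_hz must be below the Nyquist frequency")
    bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
    rate <- as.numeric(signal::filter(bf, rate))
  }
  tibble(time = seq_len(n_steps) * dt, rate = rate)
}

# Discrete prolate spheroidal sequences via the tridiagonal concentration
# operator (Percival & Walden form); cached per (n, nw, k).
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .spikecoding_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  tt <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  off <- tt[-1] * (n - tt[-1]) / 2
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), seq_len(n))] <- diag_main
  m[cbind(seq_len(n - 1), 2:n)] <- off
  m[cbind(2:n, seq_len(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
  .spikecoding_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectrum
#'
#' Power spectral density estimated with discrete prolate spheroidal (DPSS)
#' tapers. Long traces are split into half-overlapping segments of
#' `segment_length` samples; each demeaned segment is tapered with
#' `n_tapers` DPSS tapers (time-bandwidth product `nw`) and the tapered
#' periodograms are averaged with equal weights over tapers and segments.
#' The peak frequency is the argmax above `f_min_peak` (excluding DC and
#' slow drift).
#'
#' @param x Numeric trace, or a tibble with a `time` column and one value
#'   column (e.g. the output of [population_rate()]).
#' @param fs Sampling frequency (Hz); inferred from the `time` column when
#'   `x` is a tibble.
#' @param nw Time-bandwidth product.
#' @param n_tapers Number of tapers (default `2 * nw - 1`).
#' @param segment_length Samples per segment (clipped to the trace length).
#' @param f_min_peak Lowest frequency considered for the peak (Hz).
#' @return A `spectral_summary`: tibble with columns `frequency`, `power`
#'   and attributes `peak_frequency`, `peak_power`, `method`.
#' @export
power_spectrum <- function(x, fs = NULL, nw = 4, n_tapers = 2 * nw - 1,
                           segment_length = 1024, f_min_peak = 5) {
  if (is.data.frame(x)) {
    if (is.null(fs)) fs <- 1 / (x$time[2] - x$time[1])
    value_col <- setdiff(names(x), "time")[1]
    x <- x[[value_col]]
  }
  if (is.null(fs)) abort("fs must be supplied for a bare numeric trace")
  n <- length(x)
  if (n < fs) abort("trace too short: need at least 1 s of samples")
  nseg <- min(segment_length, n)
  tapers <- dpss_tapers(nseg, nw, n_tapers)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  nfreq <- floor(nseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- seg - mean(seg)
    for (j in seq_len(ncol(tapers))) {
      a <- fft(seg * tapers[, j])[seq_len(nfreq)]
      p <- (Mod(a)^2) / fs
      p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]   # one-sided
      acc <- acc + p
    }
  }
  acc <- acc / (length(starts) * ncol(tapers))
  freq <- (seq_len(nfreq) - 1L) * fs / nseg
  out <- tibble(frequency = freq, power = acc)
  sel <- freq > f_min_peak
  pk <- which.max(acc[sel])
  attr(out, "peak_frequency") <- freq[sel][pk]
  attr(out, "peak_power") <- acc[sel][pk]
  attr(out, "method") <- list(estimator = "multitaper-dpss", nw = nw,
                              n_tapers = n_tapers, segment_length = nseg,
                              n_segments = length(starts), fs = fs,
                              f_min_peak = f_min_peak)
  class(out) <- c("spectral_summary", class(out))
  out
}

#' @export
print.spectral_summary <- function(x, ...) {
  m <- attr(x, "method")
  cat(sprintf("<spectral_summary: %s, %d tapers x %d segments, peak %.1f Hz>\n",
              m$estimator, m$n_tapers, m$n_segments, attr(x, "peak_frequency")))
  NextMethod()
}

#' Peak frequency of a spectral summary
#'
#' @param spectrum A `spectral_summary` from [power_spectrum()].
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum) attr(spectrum, "peak_frequency")

#' @rdname power_spectrum
#' @param ... Unused.
#' @method glance spectral_summary
#' @export
glance.spectral_summary <- function(x, ...) {
  tibble(peak_frequency = attr(x, "peak_frequency"),
         peak_power = attr(x, "peak_power"),
         total_power = sum(x$power) * (x$frequency[2] - x$frequency[1]))
}

#' Smoothed spectrogram
#'
#' Short-time Fourier transform with a Hamming window (default 60 ms),
#' followed by causal first-order Butterworth smoothing of each frequency's
#' power time series (default cut-off 3 Hz).
#'
#' @param x Numeric trace or tibble with a `time` column.
#' @param fs Sampling frequency (Hz).
#' @param window_ms Analysis window length (ms).
#' @param step_ms Hop between windows (ms).
#' @param smoothing_cutoff_hz Cut-off of the temporal smoothing; `NULL`
#'   disables smoothing.
#' @return Tibble with columns `time`, `frequency`, `power`.
#' @export
spectrogram <- function(x, fs = NULL, window_ms = 60, step_ms = 5,
                        smoothing_cutoff_hz = 3) {
  if (is.data.frame(x)) {
    if (is.null(fs)) fs <- 1 / (x$time[2] - x$time[1])
    x <- x[[setdiff(names(x), "time")[1]]]
  }
  if (is.null(fs)) abort("fs must be supplied for a bare numeric trace")
  win <- round(window_ms / 1e3 * fs)
  step <- max(1L, round(step_ms / 1e3 * fs))
  if (win > length(x)) abort("window longer than trace")
  sg <- signal::specgram(x - mean(x), n = win, Fs = fs, overlap = win - step)
  pow <- Mod(sg$S)^2   # rows: frequency, cols: time
  if (!is.null(smoothing_cutoff_hz)) {
    frame_rate <- fs / step
    bf <- signal::butter(1, smoothing_cutoff_hz / (frame_rate / 2), type = "low")
    pow <- t(apply(pow, 1, function(row) as.numeric(signal::filter(bf, row))))
  }
  tibble(time = rep(as.numeric(sg$t), each = length(sg$f)),
         frequency = rep(as.numeric(sg$f), length(sg$t)),
         power = as.numeric(pow))
}

#' Pairwise voltage correlation and coherence
#'
#' Zero-lag Pearson correlation averaged over distinct pairs of voltage
#' traces, and the magnitude-squared coherence spectrum (smoothed
#' cross-periodogram) averaged over (up to `max_pairs`) pairs.
#'
#' @param voltage Matrix of voltage traces (samples x cells, at least 2
#'   columns).
#' @param fs Sampling frequency (Hz).
#' @param max_pairs Upper bound on the number of pairs entering the
#'   coherence average.
#' @param spans Smoothing spans passed to [stats::spec.pgram()].
#' @return List with `correlation` (scalar) and `coherence` (tibble with
#'   `frequency`, `coherence`).
#' @export
voltage_pair_statistics <- function(voltage, fs, max_pairs = 45,
                                    spans = c(25, 25)) {
  if (ncol(voltage) < 2) abort("need at least 2 voltage traces")
  sds <- apply(voltage, 2, sd)
  if (any(sds == 0)) abort("constant voltage trace: correlation undefined")
  cm <- cor(voltage)
  correlation <- mean(cm[upper.tri(cm)])
  pairs <- utils::combn(ncol(voltage), 2)
  if (ncol(pairs) > max_pairs) pairs <- pairs[, seq_len(max_pairs), drop = FALSE]
  coh_acc <- NULL
  for (j in seq_len(ncol(pairs))) {
    z <- stats::ts(voltage[, pairs[, j]], frequency = fs)
    sp <- stats::spec.pgram(z, spans = spans, taper = 0.1, plot = FALSE,
                            detrend = TRUE)
    coh_acc <- if (is.null(coh_acc)) sp$coh else coh_acc + sp$coh
  }
  list(correlation = correlation,
       coherence = tibble(frequency = sp$freq,
                          coherence = as.numeric(coh_acc) / ncol(pairs)))
}

#' Separated excitatory and inhibitory current traces
#'
#' Divides the recorded excitatory and inhibitory synaptic inputs to each
#' cell by a presumed membrane resistance; changing the resistance only
#' rescales the traces. Inhibitory cells are the default targets: they are
#' the only cells whose excitatory input (from the excitatory population) is
#' itself oscillatory, since there is no E-to-E connection and the
#' excitatory cells' excitation is the feed-forward drive.
#'
#' @param result A `sim_result` from [simulate_ei()] run with
#'   `record_inputs = TRUE`.
#' @param membrane_resistance Presumed membrane resistance (MOhm scale).
#' @param population `"inh"` or `"exc"`: whose inputs to extract.
#' @param neurons Indices of cells to include (default all).
#' @return Tibble with columns `time`, `neuron`, `excitatory`, `inhibitory`
#'   (inhibitory currents as positive magnitudes).
#' @export
extract_currents <- function(result, membrane_resistance = 5,
                             population = c("inh", "exc"), neurons = NULL) {
  population <- match.arg(population)
  if (is.null(result$inputs)) {
    abort("simulation was run without record_inputs = TRUE")
  }
  exc <- result$inputs[[if (population == "inh") "exc_on_inh" else "exc_on_exc"]]
  inh <- result$inputs[[if (population == "inh") "inh_on_inh" else "inh_on_exc"]]
  neurons <- neurons %||% seq_len(ncol(exc))
  tt <- seq_len(nrow(exc)) * result$dt
  purrr::map_dfr(neurons, function(i) {
    tibble(time = tt, neuron = i,
           excitatory = exc[, i] / membrane_resistance,
           inhibitory = inh[, i] / membrane_resistance)
  })
}

# local maxima retained only when separated from the previously retained
# peak by a trough at least `drop_fraction` below the smaller of the two
find_peaks_with_drop <- function(v, drop_fraction) {
  cand <- which(diff(sign(diff(v))) == -2) + 1L
  if (length(cand) == 0) return(integer(0))
  kept <- cand[1]
  for (p in cand[-1]) {
    last <- kept[length(kept)]
    trough <- min(v[last:p])
    if (trough <= (1 - drop_fraction) * min(v[last], v[p])) {
      kept <- c(kept, p)
    } else if (v[p] > v[last]) {
      kept[length(kept)] <- p
    }
  }
  kept
}

#' Detect and pair excitatory/inhibitory current peaks
#'
#' Local maxima of the excitatory and inhibitory current traces are retained
#' only when separated from the previously retained peak by a trough at
#' least `drop_fraction` (default 80%) below the smaller peak. Excitatory
#' and inhibitory peaks are then paired when mutually nearest and within
#' `pair_window` of each other. Lags are inhibitory minus excitatory peak
#' time, so inhibition lagging excitation gives positive lags.
#'
#' @param excitatory,inhibitory Aligned current traces (positive
#'   magnitudes).
#' @param dt Grid step (s).
#' @param drop_fraction Required fractional trough drop between retained
#'   peaks.
#' @param pair_window Maximum |lag| for pairing (s).
#' @param burn_in Initial interval (s) excluded.
#' @return A `peak_series` list: `peaks_exc`, `peaks_inh` (tibbles of `time`,
#'   `amplitude`), `pairs` (`time_exc`, `time_inh`, `lag`, `amp_exc`,
#'   `amp_inh`), and `cycles` (`amplitude` of an excitatory peak and the
#'   `next_period` to the following one).
#' @export
detect_and_pair_peaks <- function(excitatory, inhibitory, dt,
                                  drop_fraction = 0.8, pair_window = 0.015,
                                  burn_in = 0) {
  stopifnot(length(excitatory) == length(inhibitory))
  offset <- as.integer(round(burn_in / dt))
  e <- excitatory[(offset + 1):length(excitatory)]
  i <- inhibitory[(offset + 1):length(inhibitory)]
  pe <- find_peaks_with_drop(e, drop_fraction)
  pi_ <- find_peaks_with_drop(i, drop_fraction)
  te <- (pe + offset) * dt
  ti <- (pi_ + offset) * dt
  peaks_exc <- tibble(time = te, amplitude = e[pe])
  peaks_inh <- tibble(time = ti, amplitude = i[pi_])
  pairs <- tibble(time_exc = numeric(0), time_inh = numeric(0),
                  lag = numeric(0), amp_exc = numeric(0), amp_inh = numeric(0))
  if (length(te) > 0 && length(ti) > 0) {
    nearest_i <- vapply(te, function(t0) which.min(abs(ti - t0)), integer(1))
    nearest_e <- vapply(ti, function(t0) which.min(abs(te - t0)), integer(1))
    mutual <- which(nearest_e[nearest_i] == seq_along(te))
    keep <- mutual[abs(ti[nearest_i[mutual]] - te[mutual]) <= pair_window]
    pairs <- tibble(time_exc = te[keep], time_inh = ti[nearest_i[keep]],
                    lag = ti[nearest_i[keep]] - te[keep],
                    amp_exc = peaks_exc$amplitude[keep],
                    amp_inh = peaks_inh$amplitude[nearest_i[keep]])
  }
  cycles <- if (length(te) >= 2) {
    tibble(amplitude = peaks_exc$amplitude[-length(te)], next_period = diff(te))
  } else {
    tibble(amplitude = numeric(0), next_period = numeric(0))
  }
  structure(list(peaks_exc = peaks_exc, peaks_inh = peaks_inh,
                 pairs = pairs, cycles = cycles),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series: %d E peaks, %d I peaks, %d pairs, median lag %.2f ms>\n",
              nrow(x$peaks_exc), nrow(x$peaks_inh), nrow(x$pairs),
              1e3 * median(x$pairs$lag)))
  invisible(x)
}
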