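test_that("ISI statistics hit the regular and Poisson limits", {
  regular <- tibble::tibble(time = seq(0.01, 10, by = 0.01), neuron = 1L)
  expect_equal(isi_statistics(regular, "pooled")$cv, 0, tolerance = 1e-9)
  set.seed(13)
  pois <- tibble::tibble(time = sort(runif(1000, 0, 100)), neuron = 1L)
  expect_equal(isi_statistics(pois, "pooled")$cv, 1, tolerance = 0.1)
  # insufficient spikes give NA, not an error
  expect_true(is.na(isi_statistics(regular[1, ], "pooled")$cv))
})

test_that("population rate preserves the mean rate and handles empty rasters", {
  empty <- tibble::tibble(time = numeric(0), neuron = integer(0))
  pr0 <- population_rate(empty, 10, 1, 5e-4)
  expect_true(all(pr0$rate == 0))
  set.seed(14)
  spikes <- tibble::tibble(time = sort(runif(2000, 0, 10)),
                           neuron = sample(1:10, 2000, replace = TRUE))
  pr <- population_rate(spikes, 10, 10, 5e-4, cutoff_hz = 66)
  expect_equal(mean(pr$rate[pr$time > 1]), 2000 / (10 * 10), tolerance = 0.05)
})

test_that("DPSS tapers are orthonormal", {
  tp <- spikecoding:::dpss_tapers(256, 4, 7)
  gram <- crossprod(tp)
  expect_equal(gram, diag(7), tolerance = 1e-8)
})

test_that("multitaper spectrum recovers a sinusoid peak and is flat for white noise", {
  fs <- 2000
  tt <- seq(1 / fs, 3, by = 1 / fs)
  set.seed(15)
  x <- sin(2 * pi * 40 * tt) + rnorm(length(tt), sd = 0.1)
  sp <- power_spectrum(x, fs)
  expect_equal(peak_frequency(sp), 40, tolerance = 3)
  # white noise: no peak above 3x the median power, Parseval within 10%
  wn <- rnorm(3 * fs)
  spw <- power_spectrum(wn, fs)
  expect_lt(max(spw$power[spw$frequency > 5]), 3 * median(spw$power))
  expect_equal(glance(spw)$total_power, var(wn), tolerance = 0.1)
  expect_error(power_spectrum(rnorm(100), fs), "too short")
})

test_that("spectrogram shows a stationary ridge and tracks onsets", {
  fs <- 2000
  tt <- seq(1 / fs, 3, by = 1 / fs)
  x <- sin(2 * pi * 40 * tt)
  sg <- spectrogram(x, fs)
  ridge <- sg %>%
    dplyr::filter(.data$time > 0.5) %>%
    dplyr::group_by(.data$time) %>%
    dplyr::summarise(fpk = .data$frequency[which.max(.data$power)])
  expect_true(all(abs(ridge$fpk - 40) < 20))
  # step onset at 1.5 s: band power present only afterwards
  x2 <- ifelse(tt > 1.5, sin(2 * pi * 40 * tt), 0)
  sg2 <- spectrogram(x2, fs)
  band <- sg2[abs(sg2$frequency - 40) < 10, ]
  pre <- mean(band$power[band$time < 1.2])
  post <- mean(band$power[band$time > 1.9])
  expect_gt(post, 10 * pre)
  expect_error(spectrogram(rnorm(50), fs), "window longer")
})

test_that("voltage pair statistics behave for identical and independent traces", {
  set.seed(16)
  n <- 4000
  a <- rnorm(n)
  ident <- voltage_pair_statistics(cbind(a, a), fs = 1000)
  expect_equal(ident$correlation, 1)
  indep <- voltage_pair_statistics(matrix(rnorm(n * 4), ncol = 4), fs = 1000)
  expect_lt(abs(indep$correlation), 0.1)
  expect_true(all(indep$coherence$coherence >= 0 &
                    indep$coherence$coherence <= 1))
  expect_error(voltage_pair_statistics(cbind(a, rep(1, n)), 1000), "constant")
  expect_error(voltage_pair_statistics(matrix(a), 1000), "at least 2")
})

test_that("current extraction rescales with membrane resistance", {
  sim <- default_gamma_run(seed = 4, duration = 2, record_inputs = TRUE)
  c5 <- extract_currents(sim, membrane_resistance = 5, neurons = 1)
  c10 <- extract_currents(sim, membrane_resistance = 10, neurons = 1)
  expect_equal(c5$excitatory, 2 * c10$excitatory)
  expect_equal(c5$inhibitory, 2 * c10$inhibitory)
  expect_error(extract_currents(default_gamma_run(5, 1)), "record_inputs")
})

test_that("peak detection applies the trough-drop rule", {
  dt <- 1e-3
  tt <- seq(0, 1, by = dt)
  # single smooth bump
  single <- exp(-(tt - 0.5)^2 / 0.01)
  pk <- detect_and_pair_peaks(single, single, dt)
  expect_identical(nrow(pk$peaks_exc), 1L)
  # two bumps with a near-zero trough: both kept
  two <- exp(-(tt - 0.3)^2 / 0.001) + exp(-(tt - 0.7)^2 / 0.001)
  expect_identical(nrow(detect_and_pair_peaks(two, two, dt)$peaks_exc), 2L)
  # shallow trough (less than an 80% drop): merged into one peak
  shallow <- pmax(exp(-(tt - 0.3)^2 / 0.005), exp(-(tt - 0.7)^2 / 0.005), 0.5)
  expect_identical(nrow(detect_and_pair_peaks(shallow, shallow, dt)$peaks_exc), 1L)
})

test_that("peak pairing is symmetric under E/I relabelling with flipped lags", {
  dt <- 1e-3
  tt <- seq(0, 2, by = dt)
  e <- pmax(sin(2 * pi * 5 * tt), 0)
  i <- pmax(sin(2 * pi * 5 * (tt - 0.004)), 0)   # 4 ms lag
  fwd <- detect_and_pair_peaks(e, i, dt)
  rev <- detect_and_pair_peaks(i, e, dt)
  expect_equal(median(fwd$pairs$lag), 0.004, tolerance = 1e-3)
  expect_equal(sort(fwd$pairs$lag), sort(-rev$pairs$lag), tolerance = 1e-9)
})

test_that("voltage correlations fall as the injected noise grows", {
  st <- constant_stimulus(50, duration = 3, dt = 5e-4)
  cors <- vapply(c(2, 17, 60), function(sg) {
    sim <- simulate_ei(ei_config(noise_sd = sg), st, seed = 2)
    keep <- st$time > 0.5
    voltage_pair_statistics(sim$voltage$exc[keep, 1:12], fs = 2000)$correlation
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})
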