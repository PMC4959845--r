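test_that("homogeneous connectivity is the outer product of readout weights", {
  cfg <- ei_config(n_exc = 4, n_inh = 3)
  conn <- build_connectivity(cfg)
  expect_true(all(conn$w_ie == 1.44))
  expect_true(all(conn$w_ei == 1.44))
  expect_true(all(conn$w_ii == 1.44))
  expect_identical(dim(conn$w_ie), c(4L, 3L))
  expect_identical(dim(conn$w_ei), c(3L, 4L))
})

test_that("permuted connectivity preserves every neuron's summed input", {
  cfg <- ei_config(n_exc = 30, n_inh = 30, connectivity = "heterogeneous")
  set.seed(11)
  het <- build_connectivity(cfg)
  cfg$connectivity <- "permuted"
  set.seed(11)
  per <- build_connectivity(cfg)
  expect_equal(rowSums(per$w_ie), rowSums(het$w_ie))
  expect_equal(rowSums(per$w_ei), rowSums(het$w_ei))
  expect_identical(per$w_ii, het$w_ii)   # I-to-I untouched
  expect_false(identical(per$w_ie, het$w_ie))
})

test_that("heterogeneous weights follow the gamma(mean 1.2, sd 0.5) law", {
  cfg <- ei_config(n_exc = 800, n_inh = 800, connectivity = "heterogeneous")
  set.seed(5)
  conn <- build_connectivity(cfg)
  w <- c(conn$w_exc, conn$w_inh)
  expect_equal(mean(w), 1.2, tolerance = 0.05)
  expect_equal(sd(w), 0.5, tolerance = 0.1)
  expect_true(all(w > 0))
})

test_that("silent network with zero input and zero noise", {
  cfg <- ei_config(n_exc = 5, n_inh = 5, noise_sd = 0)
  st <- constant_stimulus(0, duration = 1, dt = cfg$dt)
  sim <- simulate_ei(cfg, st)
  expect_identical(nrow(sim$spikes), 0L)
  expect_true(all(sim$readout$xhat_e == 0))
  expect_true(all(sim$readout$xhat_i == 0))
})

test_that("default network fires near the unbiased-readout rate and stays balanced", {
  sim <- default_gamma_run(seed = 1, duration = 4)
  g <- glance(sim)
  expect_equal(g$rate_exc, 50 / (50 * 1.2 * 0.1), tolerance = 0.15)
  # inhibitory reconstruction tracks the excitatory one
  keep <- sim$readout$time > 0.5
  xe <- sim$readout$xhat_e[keep]
  xi <- sim$readout$xhat_i[keep]
  expect_gt(cor(xe, xi), 0.3)
  expect_lt(sqrt(mean((xe - xi)^2)), sqrt(sd(xe)^2 + sd(xi)^2))
})

test_that("recurrent drives equal the direct kernel convolution of spike trains", {
  cfg <- ei_config(n_exc = 3, n_inh = 3, noise_sd = 5)
  st <- constant_stimulus(10, duration = 1, dt = cfg$dt)
  sim <- simulate_ei(cfg, st, seed = 2, record_inputs = TRUE)
  conn <- sim$connectivity
  n_steps <- nrow(st)
  delay_bins <- round(cfg$kernel$delay / cfg$dt)
  espk <- sim$spikes[sim$spikes$population == "exc", ]
  ispk <- sim$spikes[sim$spikes$population == "inh", ]
  for (target in 1:3) {
    g_direct <- direct_convolution_drive(
      as.integer(round(espk$time / cfg$dt)), espk$neuron, conn$w_ei[target, ],
      n_steps, cfg$dt, cfg$kernel$tau_rise, cfg$kernel$tau_decay, delay_bins)
    expect_lt(max(abs(g_direct - sim$inputs$exc_on_inh[, target])), 1e-8)
    g_direct_i <- direct_convolution_drive(
      as.integer(round(ispk$time / cfg$dt)), ispk$neuron, conn$w_ie[target, ],
      n_steps, cfg$dt, cfg$kernel$tau_rise, cfg$kernel$tau_decay, delay_bins)
    expect_lt(max(abs(g_direct_i - sim$inputs$inh_on_exc[, target])), 1e-8)
  }
})

test_that("Dale's law: excitatory drives depolarize, inhibitory drives hyperpolarize", {
  sim <- default_gamma_run(seed = 3, duration = 2, record_inputs = TRUE)
  expect_true(all(sim$inputs$exc_on_inh >= 0))
  expect_true(all(sim$inputs$inh_on_inh >= 0))  # applied with negative sign
  expect_true(all(sim$inputs$inh_on_exc >= 0))
  expect_true(all(sim$inputs$exc_on_exc >= 0))
})

test_that("synaptic failures with compensation conserve expected delivered mass", {
  st <- constant_stimulus(50, duration = 4, dt = 5e-4)
  for (pf in c(0, 0.5)) {
    cfg <- ei_config(fail_prob = pf)
    sim <- simulate_ei(cfg, st, seed = 4, record_inputs = TRUE)
    espk <- sim$spikes[sim$spikes$population == "exc" & sim$spikes$time < 3.8, ]
    delivered <- sum(sim$inputs$exc_on_inh[, 1]) * cfg$dt
    expected <- sum(sim$connectivity$w_ei[1, espk$neuron])
    expect_equal(delivered / expected, 1, tolerance = 0.1)
  }
})

test_that("Poisson-substituted cells keep their reference rates and drive the readout", {
  cfg <- ei_config(poisson_fraction = 1, noise_sd = 8)
  st <- constant_stimulus(50, duration = 3, dt = cfg$dt)
  sim <- simulate_ei(cfg, st, seed = 6)
  expect_identical(length(sim$poisson_cells$exc), 50L)
  g <- glance(sim)
  # rate matching to the intact reference run
  expect_equal(g$rate_exc, 50 / (50 * 1.2 * 0.1), tolerance = 0.25)
  # spikes still enter the readout
  expect_equal(mean(sim$readout$xhat_e[st$time > 0.5]), 50, tolerance = 0.15 * 50)
})

test_that("per-neuron rates scale as 1/N with population rate invariant", {
  st <- constant_stimulus(50, duration = 3, dt = 5e-4)
  rates <- vapply(c(25, 100), function(n) {
    cfg <- ei_config(n_exc = n, n_inh = n)
    glance(simulate_ei(cfg, st, seed = 1, record_voltage = FALSE))$rate_exc
  }, numeric(1))
  expect_equal(rates[1] / rates[2], 4, tolerance = 0.15)
  expect_equal(25 * rates[1], 100 * rates[2], tolerance = 0.15 * 25 * rates[1])
})

test_that("YAML configuration round-trips", {
  path <- tempfile(fileext = ".yaml")
  cfg <- ei_config(noise_sd = 8, fail_prob = 0.2, connectivity = "heterogeneous")
  write_ei_config(cfg, path, seed = 7L)
  back <- read_ei_config(path)
  expect_equal(back$config$noise_sd, 8)
  expect_equal(back$config$fail_prob, 0.2)
  expect_identical(back$config$connectivity, "heterogeneous")
  expect_identical(back$seed, 7L)
  expect_equal(back$config$kernel$tau_decay, cfg$kernel$tau_decay)
})

test_that("mismatched stimulus grid is rejected", {
  cfg <- ei_config()
  st <- constant_stimulus(50, duration = 1, dt = 1e-3)
  expect_error(simulate_ei(cfg, st), "grid step")
})
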