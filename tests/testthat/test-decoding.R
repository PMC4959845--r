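test_that("decoder is zero for an empty raster and jumps by w at a spike", {
  dt <- 5e-4
  empty <- tibble::tibble(time = numeric(0), neuron = integer(0))
  expect_true(all(decode(empty, 1, 0.1, dt, 100)$xhat == 0))
  one <- tibble::tibble(time = 0.05, neuron = 1L)
  ro <- decode(one, 2.5, 0.1, dt, 400)
  t0 <- as.integer(0.05 / dt)
  expect_true(all(ro$xhat[seq_len(t0 - 1)] == 0))
  # forward-Euler exponential decay after the jump
  m <- 0:(400 - t0)
  expect_equal(ro$xhat[t0:400], 2.5 * (1 - dt / 0.1)^m, tolerance = 1e-12)
})

test_that("decoder is linear: merged rasters decode to the sum of decodes", {
  set.seed(8)
  dt <- 5e-4
  w <- c(1, 2, 0.5)
  mk <- function(n) tibble::tibble(time = sort(sample(1:900, n)) * dt,
                                   neuron = sample(1:3, n, replace = TRUE))
  a <- mk(40)
  b <- mk(25)
  merged <- dplyr::bind_rows(a, b)
  expect_equal(decode(merged, w, 0.1, dt, 1000)$xhat,
               decode(a, w, 0.1, dt, 1000)$xhat +
                 decode(b, w, 0.1, dt, 1000)$xhat,
               tolerance = 1e-10)
  expect_error(decode(tibble::tibble(time = dt, neuron = 5L), w, 0.1, dt, 10),
               "weight vector")
})

test_that("reconstruction error normalizations and failure modes", {
  dt <- 1e-3
  x <- rep(50, 2000)
  expect_equal(reconstruction_error(x, x, dt, 0.5, "mean"), 0)
  expect_equal(reconstruction_error(x, x + 1, dt, 0.5, "mean"), 1 / 50)
  expect_error(reconstruction_error(x, x + 1, dt, 0.5, "variance"), "zero normalizer")
  xt <- sin(seq(0, 20, length.out = 2000)) * 2 + 5
  expect_equal(reconstruction_error(xt, xt + sd(xt), dt, 0, "variance"), 1,
               tolerance = 1e-9)
})

test_that("estimation bias is the signed time-average of the residual", {
  dt <- 1e-3
  x <- rep(10, 1500)
  expect_equal(estimation_bias(x, x, dt), 0)
  expect_equal(estimation_bias(x, x - 2, dt), -2)
})

test_that("Poisson baseline fires at the requested rates and decodes", {
  expect_identical(nrow(simulate_poisson_baseline(0, 1, 0.1, 1)$spikes), 0L)
  sim <- simulate_poisson_baseline(rep(10, 20), 1, 0.1, 10, seed = 9)
  counts <- tabulate(sim$spikes$neuron, 20)
  expect_equal(mean(counts), 100, tolerance = 0.15)
  # CV of a Poisson train is near 1
  cv <- isi_statistics(sim$spikes, "per_cell")$cv
  expect_equal(cv, 1, tolerance = 0.15)
})

test_that("Poisson-baseline error falls as rates rise at fixed weights", {
  errs <- vapply(c(5, 20, 80), function(rate) {
    sim <- simulate_poisson_baseline(rep(rate, 30), 1, 0.1, 8, seed = 10)
    target <- rep(30 * rate * 0.1, length(sim$readout$xhat))
    reconstruction_error(target, sim$readout$xhat, 5e-4, 0.5, "mean")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("discrimination follows the signal-detection closed form", {
  s <- rnorm(50)
  perf0 <- discrimination_performance(s, s)
  expect_equal(perf0$d_prime, 0)
  expect_equal(perf0$p_correct, 0.5)
  # exact means 0 and 1, unit variances
  perf1 <- discrimination_performance(c(-1, 0, 1), c(0, 1, 2))
  expect_equal(perf1$d_prime, 1)
  expect_equal(perf1$p_correct, pnorm(1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(perf1$p_correct, 0.7602, tolerance = 1e-4)
  # large separation saturates towards 1
  perf_big <- discrimination_performance(c(-1, 0, 1), c(99, 100, 101))
  expect_gt(perf_big$p_correct, 0.999)
  expect_error(discrimination_performance(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(discrimination_performance(1, c(1, 2)), "2 samples")
})

test_that("p_correct stays in [0.5, 1] when the second mean is larger", {
  set.seed(12)
  for (i in 1:20) {
    mu <- runif(1, 0, 3)
    a <- rnorm(30)
    b <- rnorm(30, mean = mu)
    if (mean(b) < mean(a)) next
    p <- discrimination_performance(a, b)$p_correct
    expect_gte(p, 0.5)
    expect_lte(p, 1)
  }
})
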