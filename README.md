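# spikecoding

Simulation and analysis of **efficient-coding spiking networks with
synaptic delays** — leaky integrate-and-fire (LIF) networks whose
connectivity and dynamics are derived from a signal-reconstruction loss,
for computational neuroscientists studying how gamma-band "global
oscillations" (rhythmic population activity with sparse, irregular
single-cell firing) relate to coding efficiency and
excitation/inhibition balance.

## The model

A scalar target x(t) with dynamics τ·dx/dt = −x + c(t) is encoded by N
neurons so that a leaky readout of their spike trains,
τ·dx̂/dt = −x̂ + Σᵢ wᵢ oᵢ(t), tracks x. Each neuron fires greedily,
whenever spiking lowers the instantaneous loss

    E(t) = (x − x̂)² + α Σᵢ rᵢ + β Σᵢ rᵢ²,

which is equivalent to a LIF threshold rule with membrane voltage
Vᵢ = wᵢ(x − x̂) − β rᵢ and constant threshold Tᵢ = (wᵢ² + α + β)/2. The
biologically constrained variant obeys Dale's law — excitatory cells
encode x, inhibitory cells track the excitatory reconstruction and supply
all recurrent inhibition — with spikes transmitted through a
double-exponential synaptic current (1 ms rise, 3 ms decay, 1 ms delay)
and white membrane noise σ. Because delayed inhibition cannot always stop
neurons firing together, the network oscillates; an intermediate noise
level desynchronizes it just enough that coding error is minimized while
spikes stay entrained to a 30–50 Hz population rhythm and E/I currents
stay balanced cycle by cycle (a stochastic-resonance effect).

Main entry points:

| purpose | functions |
| --- | --- |
| stimuli | `constant_stimulus()`, `filtered_noise_stimulus()`, `command_from_target()` |
| networks | `ideal_config()`/`simulate_ideal()`, `ei_config()`/`simulate_ei()`, `build_connectivity()`, `synapse_kernel()` |
| decoding & metrics | `decode()`, `reconstruction_error()`, `estimation_bias()`, `simulate_poisson_baseline()`, `discrimination_performance()` |
| calibration | `calibrate_costs()` (bias-nulling of the L2 spike costs) |
| analysis | `isi_statistics()`, `population_rate()`, `power_spectrum()`, `spectrogram()`, `voltage_pair_statistics()`, `extract_currents()`, `detect_and_pair_peaks()` |
| experiments | `run_sweep()`, `toy_synchrony_experiment()`, `run_discrimination()` |

Results are tibbles (or light S3 objects with `tidy()`/`glance()`/
`autoplot()` methods), so everything composes with dplyr/ggplot2. A thin
command-line front end is installed as `exec/spikecoding`
(subcommands `simulate`, `sweep`, `toy`, `discriminate`).

## Worked example

Simulate the default network (50 excitatory + 50 inhibitory neurons,
readout weights 1.2, L2 cost 8.5 mV, noise 17, dt 0.5 ms) holding a
constant input of 50:

```r
library(spikecoding)

config <- ei_config()
stim   <- constant_stimulus(50, duration = 5.5, dt = config$dt)
sim    <- simulate_ei(config, stim, seed = 1, record_inputs = TRUE)
glance(sim)
#> # A tibble: 1 × 5
#>   variant duration n_spikes rate_exc rate_inh
#>   <chr>      <dbl>    <int>    <dbl>    <dbl>
#> 1 ei           5.5     4724     8.37     8.76

err  <- reconstruction_error(stim$x, sim$readout$xhat_e, config$dt, mode = "mean")
cv   <- isi_statistics(sim$spikes, "per_cell", population = "exc")$cv
rate <- population_rate(sim$spikes, 50, sim$duration, config$dt, population = "exc")
spec <- power_spectrum(rate$rate[rate$time > 0.5], fs = 1 / config$dt)
c(error = err, cv = cv, peak_hz = peak_frequency(spec))
#>   error      cv peak_hz
#>   0.060    1.24    37.1

cur <- extract_currents(sim, neurons = 1)
pk  <- detect_and_pair_peaks(cur$excitatory, cur$inhibitory, config$dt, burn_in = 0.5)
c(lag_ms = 1e3 * median(pk$pairs$lag), amp_cor = cor(pk$pairs$amp_exc, pk$pairs$amp_inh))
#>  lag_ms amp_cor
#>     3.5    0.73
```

Reading the numbers: each excitatory cell fires ~8.4 spikes/s (the
unbiased-readout rate 50/(50·1.2·0.1)), yet the population rate
oscillates with a 37 Hz spectral peak — a gamma rhythm carried by cells
that individually fire irregularly (interspike-interval CV ≈ 1.2, near
Poisson). The reconstruction stays within 6% (rms, mean-normalized) of
the target. In inhibitory cells, inhibitory current peaks trail
excitatory ones by ~3.5 ms with strongly correlated cycle amplitudes:
tight, slightly lagged E/I balance.

The stochastic-resonance u-shape over noise, with a rate-matched
independent-Poisson baseline:

```r
tab <- run_sweep(sweep_spec("noise_sweep", grid = c(2, 17, 60), seeds = 1:3,
                            duration = 5, poisson_reference = TRUE))
dplyr::summarise(dplyr::group_by(tab, value),
                 error = mean(error), mismatch = mean(ei_mismatch),
                 poisson = mean(poisson_error))
```

Coding error and the E/I reconstruction mismatch are both minimized at
the middle noise level, where the error is well below the Poisson
baseline.

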