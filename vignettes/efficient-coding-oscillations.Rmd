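---
title: "Efficient spiking coding with synaptic delays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient spiking coding with synaptic delays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package simulates recurrent networks of leaky integrate-and-fire (LIF)
neurons whose connectivity and dynamics are *derived* from a coding
objective, rather than postulated. A scalar target variable $x(t)$ obeys
first-order dynamics $\tau \dot x = -x + c(t)$, where $c(t)$ is a
feed-forward command. A population of $N$ neurons with spike trains
$o_i(t)$ supports a linear leaky readout
$\tau \dot{\hat x} = -\hat x + \sum_i w_i o_i(t)$, and each neuron fires
greedily: it spikes exactly when doing so lowers the instantaneous loss

$$E(t) = (x - \hat x)^2 + \alpha \sum_i r_i + \beta \sum_i r_i^2,$$

where $r_i$ is a leaky trace of the neuron's own spikes and $\alpha,\beta$
are L1/L2 spike costs. The greedy rule is algebraically identical to a
threshold rule: defining the membrane voltage
$V_i = w_i (x - \hat x) - \beta r_i$, the neuron fires iff
$V_i > T_i = \tfrac12 (w_i^2 + \alpha + \beta)$. Differentiating $V_i$
yields LIF dynamics with leak, feed-forward drive $w_i c(t)$, recurrent
inhibition $-w_i w_k$ per spike of neuron $k$, and a self-reset $-\beta$.
`spike_threshold()`, `membrane_voltage()`, `coding_loss()` expose these
pieces; `simulate_ideal()` integrates the instantaneous-synapse network.

The biologically constrained variant (`simulate_ei()`) splits the circuit
into excitatory cells (which encode $x$ and receive the feed-forward drive)
and inhibitory cells (which minimise $(\hat x_I - \hat x_E)^2$ plus their own
spike costs, and supply *all* recurrent inhibition). There is no E→E
connection; connection strengths are outer products of readout weights, so
reciprocal E/I connections are matched ("precisely balanced"). Cross-neuron
spike effects pass through a double-exponential synaptic current

$$h(t) \propto e^{-(t-\tau_{tr})/\tau_d} - e^{-(t-\tau_{tr})/\tau_r}
\quad (t > \tau_{tr}),$$

normalised to unit integral, with rise 1 ms, decay 3 ms and transmission
delay 1 ms by default. Delayed inhibition cannot always prevent neurons from
firing together; the resulting dynamics are rhythmic population bursts
(gamma band at the default operating point) in which each neuron
participates sparsely and irregularly.

## Spike-impulse convention and discretization

The differential equations mix $\tau$-scaled dynamics with Dirac spike
trains. The package adopts the only convention consistent with the
threshold derivation: one spike of neuron $i$ increments the readout by
$w_i$ and the rate trace $r_i$ by 1, and decrements voltages by the
coefficient of the corresponding spike-train term ($w_k w_i$ recurrent,
$\beta$ self-reset). With readout weight 1.2 this makes the postsynaptic
potential $w^2 = 1.44$ mV, and the biophysical mapping
(`biophysical_mapping()`) places rest 4.97 mV below a −55 mV threshold and
the reset 9.94 mV below it.

Integration is forward Euler at `dt = 0.5` ms. Between spikes the readout
and rate traces decay by the factor $(1 - dt/\tau)$ per step — the Euler
discretization rather than $e^{-dt/\tau}$ — so that the integrated voltage
and the closed form $w(x - \hat x) - \beta r$ agree to machine precision,
which the test suite exploits as an exact oracle. In the ideal network at
most one neuron (the most supra-threshold one; ties to the lowest index)
fires per bin; in the delayed network any number may fire per bin, which is
what allows the synchronous-pathology regime to exist at all.

Voltage noise is added per step as $\sigma \sqrt{dt/\tau}\,\xi$ with
$\xi \sim \mathcal N(0,1)$, i.e. unit-variance white noise with the
dynamics written in units of the membrane time constant; the stationary
voltage SD is then $\sigma/\sqrt 2$, independent of `dt` and `tau`. We
chose this reading of the noise term over the alternative
$\sigma\sqrt{dt}$ (stationary SD $\sigma\sqrt{\tau/2}$) on empirical
grounds: only with $\sigma\sqrt{dt/\tau}$ does the standard noise scale
$\sigma = 17$ sit at the network's own optimum, where simultaneously (i)
the coding error is minimised over noise, (ii) the per-cell interspike CV
is near 1, (iii) the population rhythm peaks in the 30–50 Hz band, and
(iv) the bias-nulling calibration returns the L2 cost to its nominal
8.5 mV. Under the alternative reading all four signatures instead align
near $\sigma \approx 50$.

The synaptic convolution is realised by exact two-state exponential
filters per postsynaptic target plus a delay ring buffer; impulses are
scaled by the discrete kernel mass so that the summed delivered drive per
spike equals the connection weight exactly on the grid (a direct
discrete-convolution oracle in the tests confirms equivalence). The
self-reset is applied instantaneously, not through the kernel: it models
intracellular dynamics, not a synapse.

## Noise manipulations

Three ways of desynchronising the network are implemented, matching the
sweep experiments:

* **Membrane noise** (`noise_sd`), as above.
* **Synaptic failures** (`fail_prob`): each (spike, target) transmission is
  deleted independently with probability $p$; surviving recurrent weights
  are divided by the delivery probability $1-p$ so the *expected* delivered
  mass per spike is unchanged. (Dividing by $p$ itself, a literal reading
  of the protocol, diverges as $p \to 0$; the delivery-probability reading
  is used.)
* **Poisson substitution** (`poisson_fraction`): a random subset of cells
  fires independent Poisson trains whose rates are measured from a
  reference run of the intact network at the same parameters; their spikes
  still enter recurrence and the readout, while their own inputs are
  ignored.

Because any of these changes firing rates and hence introduces estimation
bias, `calibrate_costs()` implements bias-nulling: simulation chunks of
2 s (after a 0.5 s burn-in) are alternated with cost updates
$\beta \leftarrow \beta + \eta\, \mathrm{bias}$, $\eta = 0.5$, separately
for the excitatory bias (mean of $\hat x_E - x$) and the inhibitory bias
(mean of $\hat x_I - \hat x_E$; the inhibitory code targets the excitatory
reconstruction), until both are below 0.5 on a target of 50 (1%), with a
50-chunk budget. The spike threshold co-varies with $\beta$ through the
threshold formula, which is precisely what holds firing rates constant
across noise levels. The chunk length, learning rate and tolerance are the
package's own choices (the procedure is specified only qualitatively in
the literature); downstream results condition only on the calibrated
state, not on the schedule.

## Stimuli

`constant_stimulus()` and `filtered_noise_stimulus()` generate the two
stimulus families used throughout: constants (amplitudes 4 for the
three-neuron toy network; 35/50/65 for the amplitude set; 48 for
discrimination), and white noise low-pass filtered by a causal first-order
Butterworth filter (cut-offs 4 Hz or 2 Hz) then affinely rescaled so the
realized sample mean and SD match the requested values exactly. Filtering
is causal (forward-only) — an online stimulus — rather than zero-phase;
only the filter design is specified by the source protocol, and causal is
the conservative choice. The command trace is recovered from the target by
forward differences (`command_from_target()`), which makes Euler
integration of the target dynamics reproduce the target exactly on the
grid.

These generators emulate the study conditions, not natural stimuli: they
are one-dimensional, stationary, and noise-free at the input. Passing
tests therefore demonstrates correctness of the coding machinery under
those conditions, and says nothing about high-dimensional or
non-stationary inputs.

## Analysis choices

* **Population rate**: binned spike counts per neuron per `dt`, expressed
  in spikes/s/neuron, optionally low-pass filtered (causal first-order
  Butterworth; 5.5 Hz for slow envelopes, 66 Hz for cycle-resolved views).
* **Power spectra** (`power_spectrum()`): multitaper estimation with DPSS
  tapers computed from the tridiagonal concentration operator. Long traces
  are split into half-overlapping 1024-sample segments and tapered
  periodograms are averaged over tapers and segments with equal weights.
  Time-bandwidth product 4 with 7 tapers by default. Equal-weight averaging
  (rather than Thomson's adaptive weights) is used deliberately: with 7
  well-concentrated tapers the difference is negligible for the only
  quantity consumed downstream, the location of the spectral peak, and the
  estimator stays simple and fast. The peak is the argmax above 5 Hz,
  excluding DC and slow drift. Band-level conclusions (e.g. "peak in
  30–50 Hz") are robust to the bandwidth; exact peak shapes are not
  asserted anywhere.
* **Spectrogram** (`spectrogram()`): short-time Fourier transform with a
  60 ms Hamming window, 5 ms hop, each frequency's power time series
  smoothed by a causal first-order Butterworth filter at 3 Hz.
* **Voltage statistics** (`voltage_pair_statistics()`): the scalar summary
  is the zero-lag Pearson correlation averaged over distinct pairs; the
  coherence spectrum is the smoothed cross-periodogram (magnitude-squared
  coherency) averaged over pairs.
* **E/I currents** (`extract_currents()`): separated synaptic drives
  divided by a presumed 5 MΩ membrane resistance (pure rescaling).
  Inhibitory cells are the default targets: with no E→E connection the
  excitatory population's only excitation is the constant feed-forward
  drive, so oscillating excitatory *and* inhibitory currents coexist only
  in inhibitory targets.
* **Peak pairing** (`detect_and_pair_peaks()`): local maxima are retained
  only when separated from the previously retained peak by a trough at
  least 80% below the smaller of the two (the "80% drop" read as: the
  trough descends below 20% of the smaller adjacent peak). E and I peaks
  are paired when mutually nearest and within 15 ms; the lag is I minus E
  time. The cycle table pairs each excitatory peak amplitude with the
  interval to the next excitatory peak (Pearson correlation of the two is
  the amplitude–period coupling statistic).

## Experiments and problem sizes

`run_sweep()` drives the scripted experiments (noise, synaptic failure,
Poisson fraction, amplitude set, network size, inhibitory size, kernel
time-constant scale, readout time constant, heterogeneous vs permuted
connectivity). Defaults are 3 seeds and 5–10 s of simulated time per grid
point with a 0.5 s burn-in — enough that the orderings asserted in the
tests (u-shapes, monotonicities, 1/N rate scaling) are stable across
seeds, while a full sweep still runs in well under a minute. Sweep grids
are coarse and bracketing by design (e.g. noise $\sigma \in \{2, 17, 60\}$
around the optimum): the source protocol does not print its grids or
durations, so the package asserts orderings, never curve shapes.

For the discrimination experiment (`run_discrimination()`), two constant
stimuli straddle a centre amplitude of 48; after calibration at the
centre, long runs at each amplitude are carved into 0.1 s segments, the
excitatory readout is time-averaged per segment, and the two estimate
samples enter the standard signal-detection computation
$d = (\mu_2-\mu_1)/\sqrt{(\sigma_1^2+\sigma_2^2)/2}$,
$p_\mathrm{correct} = \Phi(d/\sqrt 2)$. The printed form of this mapping
in the source is typographically garbled (it would dip below chance for
positive $d$); the standard two-alternative form, which is 1/2 at $d=0$
and increasing, is used. The amplitude separation is a free parameter
(the source does not print it); 4 is the default.

In the synchrony toy model (`toy_synchrony_experiment()`), 10 neurons fire
on a perfectly regular population schedule with $k$ cells synchronous per
event and the total rate fixed at 200 spikes/s (the source prints no rate;
200 — 20 spikes per readout time constant — makes the fully synchronous
schedule and the Poisson reference distinguishable at the analytic level:
regular-schedule error $k/(R\tau\sqrt{12})$ vs Poisson error
$1/\sqrt{2R\tau}$). Error grows linearly in $k$, and matched-rate
independent Poisson firing is worse than every regular schedule.

## Degenerate inputs and numerical safeguards

Constant targets reject the variance-normalized error mode (zero
normalizer); zero-mean targets reject the mean-normalized mode. Stimulus
cut-offs at or above Nyquist are rejected. The kernel requires
$\tau_d > \tau_r > 0$ (the normalization degenerates at equality). Spectra
require at least 1 s of samples. Simulator divergence (|V| > 10^8 or
non-finite) aborts with a diagnostic rather than returning garbage.
Exact ties in the ideal network's one-spike-per-bin argmax go to the
lowest neuron index, making runs bit-reproducible given a seed.

## Known limitations

* Synapses are voltage-driven, not conductance-based; membrane time
  constants are the 100 ms readout timescale, slower than cortical
  membranes.
* Inputs are one-dimensional; heterogeneity is limited to gamma-distributed
  readout weights.
* The multitaper estimator averages over segments, trading frequency
  resolution (about 2 Hz at the default 2 kHz sampling) for variance; peak
  *band* statements are reliable, narrow line shapes are not.
* Calibration assumes a constant target; time-varying targets would need a
  slower bias estimator.
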