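#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the ideal (instantaneous-synapse) efficient
// coding network. Spikes act impulsively: one spike of neuron s decrements
// every voltage by w_k * w_s, decrements the spiker by an additional l2
// (reset), increments the spiker's rate trace by 1 and the readout by w_s.
// At most one neuron (the one with the highest supra-threshold voltage) may
// fire per bin; exact ties go to the lowest index.
// [[Rcpp::export]]
List simulate_ideal_cpp(NumericVector w, double l1, double l2,
                        double tau, double sigma, double dt,
                        NumericVector cmd) {
  const int n = w.size();
  const int nt = cmd.size();
  const double a = dt / tau;
  const double sq = std::sqrt(dt / tau);

  NumericVector V(n), r(n), thr(n);
  for (int i = 0; i < n; ++i) thr[i] = 0.5 * (w[i] * w[i] + l1 + l2);

  NumericMatrix Vout(nt, n), rout(nt, n);
  NumericVector xhat(nt);
  std::vector<int> spike_bin;
  std::vector<int> spike_neuron;
  double xh = 0.0;

  for (int t = 0; t < nt; ++t) {
    xh *= (1.0 - a);
    for (int i = 0; i < n; ++i) {
      r[i] *= (1.0 - a);
      V[i] += a * (-V[i] + w[i] * cmd[t]);
      if (sigma > 0.0) V[i] += sigma * sq * norm_rand();
    }
    // one spike per bin: strict argmax among supra-threshold neurons
    int s = -1;
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
      if (V[i] > thr[i] && (s < 0 || V[i] > best)) { s = i; best = V[i]; }
    }
    if (s >= 0) {
      for (int k = 0; k < n; ++k) V[k] -= w[k] * w[s];
      V[s] -= l2;
      r[s] += 1.0;
      xh += w[s];
      spike_bin.push_back(t + 1);
      spike_neuron.push_back(s + 1);
    }
    for (int i = 0; i < n; ++i) {
      if (!R_finite(V[i]) || std::fabs(V[i]) > 1e8)
        stop("ideal network integration diverged (|V| > 1e8 at step %d)", t + 1);
      Vout(t, i) = V[i];
      rout(t, i) = r[i];
    }
    xhat[t] = xh;
  }

  return List::create(_["spike_bin"] = wrap(spike_bin),
                      _["spike_neuron"] = wrap(spike_neuron),
                      _["voltage"] = Vout,
                      _["rate"] = rout,
                      _["readout"] = xhat);
}

// Delayed-synapse excitatory/inhibitory network (Dale's law).  Cross-neuron
// spike effects are convolved with a difference-of-exponentials synaptic
// kernel (rise tau_r, decay tau_d, transmission delay delay_bins * dt),
// realized by exact two-state exponential filters plus a delay ring buffer.
// Impulse amounts are scaled so the discrete delivered mass per spike equals
// the connection weight exactly.  Own-spike resets are instantaneous.  Any
// number of neurons may fire per bin.  Per-(spike, target) Bernoulli
// transmission failures scale surviving weights by 1/(1 - fail_prob).
// Poisson-substituted cells fire at fixed rates; their spikes still enter
// recurrence and readout, their own inputs are ignored.
// [[Rcpp::export]]
List simulate_ei_cpp(NumericVector wE, NumericVector wI,
                     double l1E, double l2E, double l1I, double l2I,
                     double tau, double sigma, double dt, NumericVector cmd,
                     NumericMatrix Wei,  // nE x nI : I -> E
                     NumericMatrix Wie,  // nI x nE : E -> I
                     NumericMatrix Wii,  // nI x nI : I -> I
                     double tau_r, double tau_d, int delay_bins,
                     double fail_prob,
                     LogicalVector poisE, LogicalVector poisI,
                     NumericVector rateE, NumericVector rateI,
                     bool record_voltage, bool record_inputs) {
  const int nE = wE.size();
  const int nI = wI.size();
  const int nt = cmd.size();
  const double a = dt / tau;
  const double sq = std::sqrt(dt / tau);
  const double qd = std::exp(-dt / tau_d);
  const double qr = std::exp(-dt / tau_r);
  // discrete kernel mass: sum_m (qd^m - qr^m) = 1/(1-qd) - 1/(1-qr)
  const double mass = 1.0 / (1.0 - qd) - 1.0 / (1.0 - qr);
  const double scale = 1.0 / (dt * mass);
  const double psucc = 1.0 - fail_prob;
  const double inv_ps = 1.0 / psucc;
  const bool failures = fail_prob > 0.0;
  const int L = delay_bins + 1;

  NumericVector thrE(nE), thrI(nI);
  for (int i = 0; i < nE; ++i) thrE[i] = 0.5 * (wE[i] * wE[i] + l1E + l2E);
  for (int i = 0; i < nI; ++i) thrI[i] = 0.5 * (wI[i] * wI[i] + l1I + l2I);

  // synaptic filter states per postsynaptic target
  NumericVector eI_d(nE), eI_r(nE);              // I drive onto E cells
  NumericVector iE_d(nI), iE_r(nI);              // E drive onto I cells
  NumericVector iI_d(nI), iI_r(nI);              // I drive onto I cells
  // delay ring buffers of pending impulses
  NumericMatrix bufEI(L, nE), bufIE(L, nI), bufII(L, nI);

  NumericVector VE(nE), VI(nI);
  NumericVector xhatE(nt), xhatI(nt);
  NumericMatrix VEout, VIout, excI_in, inhI_in, excE_in, inhE_in;
  if (record_voltage) { VEout = NumericMatrix(nt, nE); VIout = NumericMatrix(nt, nI); }
  if (record_inputs) {
    excI_in = NumericMatrix(nt, nI); inhI_in = NumericMatrix(nt, nI);
    excE_in = NumericMatrix(nt, nE); inhE_in = NumericMatrix(nt, nE);
  }
  std::vector<int> sbinE, sneurE, sbinI, sneurI;
  std::vector<int> firedE(nE), firedI(nI);
  double xhE = 0.0, xhI = 0.0;

  for (int t = 0; t < nt; ++t) {
    const int slot = t % L;
    // deliver impulses arriving this bin (instantaneous drive is zero since
    // the two filter states cancel at arrival: the kernel is 0 at t = delay)
    for (int i = 0; i < nE; ++i) {
      const double b = bufEI(slot, i);
      if (b != 0.0) { eI_d[i] += b; eI_r[i] += b; bufEI(slot, i) = 0.0; }
    }
    for (int i = 0; i < nI; ++i) {
      double b = bufIE(slot, i);
      if (b != 0.0) { iE_d[i] += b; iE_r[i] += b; bufIE(slot, i) = 0.0; }
      b = bufII(slot, i);
      if (b != 0.0) { iI_d[i] += b; iI_r[i] += b; bufII(slot, i) = 0.0; }
    }

    xhE *= (1.0 - a);
    xhI *= (1.0 - a);

    // voltages (noise drawn for every cell to keep the stream aligned)
    for (int i = 0; i < nE; ++i) {
      const double gI = (eI_d[i] - eI_r[i]) * scale;
      const double xi = sigma > 0.0 ? sigma * sq * norm_rand() : 0.0;
      VE[i] += a * (-VE[i] + wE[i] * cmd[t]) - dt * gI + xi;
      if (record_inputs) { excE_in(t, i) = wE[i] * cmd[t] / tau; inhE_in(t, i) = gI; }
    }
    for (int i = 0; i < nI; ++i) {
      const double gE = (iE_d[i] - iE_r[i]) * scale;
      const double gI = (iI_d[i] - iI_r[i]) * scale;
      const double xi = sigma > 0.0 ? sigma * sq * norm_rand() : 0.0;
      VI[i] += a * (-VI[i]) + dt * (gE - gI) + xi;
      if (record_inputs) { excI_in(t, i) = gE; inhI_in(t, i) = gI; }
    }

    // decay filter states (after the drive is read: first nonzero drive
    // appears one bin after arrival, i.e. strictly after the delay)
    for (int i = 0; i < nE; ++i) { eI_d[i] *= qd; eI_r[i] *= qr; }
    for (int i = 0; i < nI; ++i) { iE_d[i] *= qd; iE_r[i] *= qr; iI_d[i] *= qd; iI_r[i] *= qr; }

    // spike decisions (simultaneous, from post-update voltages)
    for (int i = 0; i < nE; ++i)
      firedE[i] = poisE[i] ? (unif_rand() < rateE[i] * dt) : (VE[i] > thrE[i]);
    for (int i = 0; i < nI; ++i)
      firedI[i] = poisI[i] ? (unif_rand() < rateI[i] * dt) : (VI[i] > thrI[i]);

    const int arrive = (t + delay_bins) % L;
    for (int k = 0; k < nE; ++k) {
      if (!firedE[k]) continue;
      VE[k] -= l2E;
      xhE += wE[k];
      sbinE.push_back(t + 1); sneurE.push_back(k + 1);
      for (int i = 0; i < nI; ++i) {
        if (!failures || unif_rand() < psucc)
          bufIE(arrive, i) += Wie(i, k) * (failures ? inv_ps : 1.0);
      }
    }
    for (int k = 0; k < nI; ++k) {
      if (!firedI[k]) continue;
      VI[k] -= l2I;
      xhI += wI[k];
      sbinI.push_back(t + 1); sneurI.push_back(k + 1);
      for (int i = 0; i < nE; ++i) {
        if (!failures || unif_rand() < psucc)
          bufEI(arrive, i) += Wei(i, k) * (failures ? inv_ps : 1.0);
      }
      for (int i = 0; i < nI; ++i) {
        if (!failures || unif_rand() < psucc)
          bufII(arrive, i) += Wii(i, k) * (failures ? inv_ps : 1.0);
      }
    }

    for (int i = 0; i < nE; ++i)
      if (!R_finite(VE[i]) || std::fabs(VE[i]) > 1e8)
        stop("E/I network integration diverged (|V| > 1e8 at step %d)", t + 1);

    if (record_voltage) {
      for (int i = 0; i < nE; ++i) VEout(t, i) = VE[i];
      for (int i = 0; i < nI; ++i) VIout(t, i) = VI[i];
    }
    xhatE[t] = xhE;
    xhatI[t] = xhI;
  }

  List out = List::create(_["spike_bin_e"] = wrap(sbinE),
                          _["spike_neuron_e"] = wrap(sneurE),
                          _["spike_bin_i"] = wrap(sbinI),
                          _["spike_neuron_i"] = wrap(sneurI),
                          _["readout_e"] = xhatE,
                          _["readout_i"] = xhatI);
  if (record_voltage) { out["voltage_e"] = VEout; out["voltage_i"] = VIout; }
  if (record_inputs) {
    out["exc_input_e"] = excE_in; out["inh_input_e"] = inhE_in;
    out["exc_input_i"] = excI_in; out["inh_input_i"] = inhI_in;
  }
  return out;
}
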