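#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Piece-wise linear leak: total state decrement for an elapsed interval of
// `dt` microseconds. `brk` holds the halving breakpoints (elapsed us,
// strictly increasing), `slp` the per-segment slopes in state-units/us
// (length(brk) + 1). Clamping at zero happens at the counter, not here.
static inline double leak_amount(double dt, const NumericVector& brk,
                                 const NumericVector& slp) {
  double amt = 0.0, prev = 0.0;
  const int K = brk.size();
  for (int k = 0; k < K; ++k) {
    if (dt <= brk[k]) return amt + slp[k] * (dt - prev);
    amt += slp[k] * (brk[k] - prev);
    prev = brk[k];
  }
  return amt + slp[K] * (dt - prev);
}

// Event-driven integration of one fully connected population.
//
// ev_addr: 0-based input addresses; ev_time: non-decreasing microseconds.
// W: n_pre x n_post integer weight matrix, modified in place (caller clones).
// firing_th / stdp_th: per-neuron thresholds, modified in place.
// stdp_cb: R callback (j_1based, buffer, column) -> new column; it owns the
// weight-update rule so that exactly one STDP implementation exists.
// RNG: uses R's stream; state is handed back to R around each callback.
// [[Rcpp::export]]
List cpp_run_events(IntegerVector ev_addr, NumericVector ev_time,
                    IntegerMatrix W,
                    NumericVector firing_th, NumericVector stdp_th,
                    double x_th_max, double th_increment,
                    bool dual_threshold, double stdp_th_increment,
                    bool learn, bool wta, bool wta_random,
                    bool adapt_thresholds,
                    bool leak_on, NumericVector leak_breaks,
                    NumericVector leak_slopes,
                    int buffer_size, bool flush,
                    bool record_spikes,
                    Function stdp_cb)
{
  const int nE = ev_addr.size();
  const int nPre = W.nrow();
  const int nPost = W.ncol();
  std::vector<double> f(nPost, 0.0), l(nPost, 0.0);
  double last = nE ? ev_time[0] : 0.0;
  std::deque<int> buf;
  std::vector<int> spk_n;
  std::vector<double> spk_t;
  IntegerVector counts(nPost), stdp_counts(nPost);

  // run the R weight-update rule for neuron j (0-based)
  auto do_stdp = [&](int j) {
    IntegerVector bufv(buf.begin(), buf.end());
    IntegerVector col(nPre);
    for (int i = 0; i < nPre; ++i) col[i] = W(i, j);
    PutRNGstate();                     // sync R RNG before callback draws
    IntegerVector newcol = as<IntegerVector>(stdp_cb(j + 1, bufv, col));
    GetRNGstate();
    for (int i = 0; i < nPre; ++i) W(i, j) = newcol[i];
    l[j] = 0.0;
    if (dual_threshold) stdp_th[j] += stdp_th_increment;
    stdp_counts[j]++;
    if (flush) buf.clear();
  };

  auto emit_spike = [&](int j, double t) {
    counts[j]++;
    if (record_spikes) { spk_n.push_back(j + 1); spk_t.push_back(t); }
    f[j] = 0.0;
    if (!dual_threshold) l[j] = 0.0;   // single-state mode: one counter pair
    if (adapt_thresholds) {
      firing_th[j] += th_increment;
      if (firing_th[j] > x_th_max) firing_th[j] = x_th_max;
    }
  };

  for (int e = 0; e < nE; ++e) {
    const int a = ev_addr[e];
    const double t = ev_time[e];
    if (leak_on) {
      const double dt = t - last;
      if (dt > 0) {
        const double amt = leak_amount(dt, leak_breaks, leak_slopes);
        for (int j = 0; j < nPost; ++j) {
          f[j] -= amt; if (f[j] < 0) f[j] = 0;
          l[j] -= amt; if (l[j] < 0) l[j] = 0;
        }
      }
    }
    last = t;

    buf.push_back(a);
    if ((int)buf.size() > buffer_size) buf.pop_front();

    std::vector<int> fired;
    for (int j = 0; j < nPost; ++j) {
      const int w = W(a, j);
      if (w > 0) { f[j] += w; l[j] += w; }
      if (f[j] >= firing_th[j]) fired.push_back(j);
    }

    if (wta) {
      if (!fired.empty()) {
        int winner = fired[0];
        if (fired.size() > 1 && wta_random) {
          int k = (int)std::floor(unif_rand() * fired.size());
          if (k >= (int)fired.size()) k = fired.size() - 1;
          winner = fired[k];
        }
        // lateral inhibition: reset every other neuron in the population
        for (int j = 0; j < nPost; ++j)
          if (j != winner) { f[j] = 0.0; l[j] = 0.0; }
        const bool trig = learn &&
          (dual_threshold ? (l[winner] >= stdp_th[winner]) : true);
        emit_spike(winner, t);
        if (trig) do_stdp(winner);
      } else if (learn && dual_threshold) {
        // STDP trigger can occur without a firing-threshold crossing
        int cand = -1;
        for (int j = 0; j < nPost; ++j)
          if (l[j] >= stdp_th[j]) { cand = j; break; }
        if (cand >= 0) {
          for (int j = 0; j < nPost; ++j) if (j != cand) l[j] = 0.0;
          do_stdp(cand);
        }
      }
    } else {
      for (size_t k = 0; k < fired.size(); ++k) {
        const int j = fired[k];
        const bool trig = learn && !dual_threshold;
        emit_spike(j, t);
        if (trig) do_stdp(j);
      }
      if (learn && dual_threshold)
        for (int j = 0; j < nPost; ++j)
          if (l[j] >= stdp_th[j]) do_stdp(j);
    }
  }

  return List::create(
    _["weights"] = W,
    _["firingThresholds"] = firing_th,
    _["stdpThresholds"] = stdp_th,
    _["spikeCounts"] = counts,
    _["stdpCounts"] = stdp_counts,
    _["firingCounters"] = NumericVector(f.begin(), f.end()),
    _["learningCounters"] = NumericVector(l.begin(), l.end()),
    _["spikeNeurons"] = IntegerVector(spk_n.begin(), spk_n.end()),
    _["spikeTimes"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["buffer"] = IntegerVector(buf.begin(), buf.end()));
}

// Integrate-and-fire output layer used by the converted softmax classifier.
// Weights may exceed the threshold, so firing uses reset-by-subtraction and
// an event may yield several output spikes ("zero" mode resets instead).
// [[Rcpp::export]]
IntegerVector cpp_snn_counts(IntegerVector ev_addr, IntegerMatrix W,
                             double threshold, bool subtract_reset) {
  const int nE = ev_addr.size();
  const int nPost = W.ncol();
  std::vector<double> v(nPost, 0.0);
  IntegerVector counts(nPost);
  for (int e = 0; e < nE; ++e) {
    const int a = ev_addr[e];
    for (int j = 0; j < nPost; ++j) {
      v[j] += W(a, j);
      if (v[j] >= threshold) {
        if (subtract_reset) {
          const int k = (int)std::floor(v[j] / threshold);
          counts[j] += k;
          v[j] -= k * threshold;
        } else {
          counts[j] += 1;
          v[j] = 0.0;
        }
      }
    }
  }
  return counts;
}

// Fibonacci LFSR over a 16-bit register, shift-left, XOR feedback from the
// given taps (1-based bit positions, bit 16 = MSB). Returns the successive
// states and their low-10-bit samples.
// [[Rcpp::export]]
List cpp_lfsr_sequence(int state, IntegerVector taps, int n) {
  IntegerVector states(n), samples(n);
  unsigned int s = (unsigned int)state & 0xFFFFu;
  const int T = taps.size();
  for (int i = 0; i < n; ++i) {
    unsigned int fb = 0;
    for (int k = 0; k < T; ++k) fb ^= (s >> (taps[k] - 1)) & 1u;
    s = ((s << 1) | fb) & 0xFFFFu;
    states[i] = (int)s;
    samples[i] = (int)(s & 0x3FFu);
  }
  return List::create(_["state"] = states, _["sample"] = samples);
}
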