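#include <Rcpp.h>
using namespace Rcpp;

// Exact evaluation of first-order exponential filters driven by a binary
// pulse train. All kernels are piecewise-exponential between pulse edges, so
// states are propagated in closed form through the sorted edge times and then
// read out at the (sorted) sample times; no integration step is involved.

// I(t) = (1/tau) int_0^t e^{-(t-s)/tau} S(s) ds, S = 1 on [onset, offset).
// [[Rcpp::export]]
NumericVector cpp_exp_filter(NumericVector t, NumericVector onsets,
                             NumericVector offsets, double tau) {
  const int n = t.size(), m = onsets.size();
  NumericVector out(n);
  if (tau <= 0) stop("tau must be > 0");
  double state = 0.0, tcur = (n > 0 && t[0] < 0) ? t[0] : 0.0;
  int s = 0;            // current signal value
  int ei = 0;           // next edge index (2m edges interleaved)
  int i = 0;
  while (i < n) {
    // next edge time (onsets[ei/2] when even state boundary)
    double tedge = R_PosInf;
    int snew = s;
    if (ei < 2 * m) {
      int k = ei / 2;
      if (ei % 2 == 0) { tedge = onsets[k]; snew = 1; }
      else             { tedge = offsets[k]; snew = 0; }
    }
    if (t[i] < tedge) {
      double v = s + (state - s) * std::exp(-(t[i] - tcur) / tau);
      out[i] = v;
      ++i;
    } else {
      state = s + (state - s) * std::exp(-(tedge - tcur) / tau);
      tcur = tedge;
      s = snew;
      ++ei;
    }
  }
  return out;
}

// Novelty response: spikes to A at each onset, decays with tau_nd between
// onsets. A = 1 for the first onset, 1 - exp(-(gap)/tau_n) afterwards.
// [[Rcpp::export]]
NumericVector cpp_novelty(NumericVector t, NumericVector onsets,
                          double tau_n, double tau_nd) {
  const int n = t.size(), m = onsets.size();
  NumericVector out(n);
  if (m == 0) return out;
  int k = -1;                  // index of latest onset <= t
  double amp = 0.0;
  for (int i = 0; i < n; ++i) {
    while (k + 1 < m && onsets[k + 1] <= t[i]) {
      ++k;
      amp = (k == 0) ? 1.0 : 1.0 - std::exp(-(onsets[k] - onsets[k - 1]) / tau_n);
    }
    out[i] = (k < 0) ? 0.0 : amp * std::exp(-(t[i] - onsets[k]) / tau_nd);
  }
  return out;
}

// Onset-frequency filter: unit increment at each onset, exponential decay
// with tau in between (running estimate of encounter frequency).
// [[Rcpp::export]]
NumericVector cpp_onset_filter(NumericVector t, NumericVector onsets,
                               double tau) {
  const int n = t.size(), m = onsets.size();
  NumericVector out(n);
  double state = 0.0, tcur = R_NegInf;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k < m && onsets[k] <= t[i]) {
      if (R_finite(tcur)) state *= std::exp(-(onsets[k] - tcur) / tau);
      state += 1.0;
      tcur = onsets[k];
      ++k;
    }
    out[i] = R_finite(tcur) ? state * std::exp(-(t[i] - tcur) / tau) : 0.0;
  }
  return out;
}

// Two-timescale integrator: relaxes toward 1 with tau_g while the signal is
// on, decays with tau_d while it is off. tau_g = 0 is the instantaneous-rise
// limit (R jumps to 1 during signal); tau_d = 0 resets R at offsets.
// [[Rcpp::export]]
NumericVector cpp_two_timescale(NumericVector t, NumericVector onsets,
                                NumericVector offsets, double tau_g,
                                double tau_d) {
  const int n = t.size(), m = onsets.size();
  NumericVector out(n);
  double state = 0.0, tcur = (n > 0 && t[0] < 0) ? t[0] : 0.0;
  int s = 0, ei = 0, i = 0;
  auto prop = [&](double from, double to, double st) {
    if (to <= from) return st;
    if (s == 1) {
      if (tau_g <= 0) return 1.0;
      return 1.0 + (st - 1.0) * std::exp(-(to - from) / tau_g);
    }
    if (tau_d <= 0) return 0.0;
    return st * std::exp(-(to - from) / tau_d);
  };
  while (i < n) {
    double tedge = R_PosInf;
    int snew = s;
    if (ei < 2 * m) {
      int k = ei / 2;
      if (ei % 2 == 0) { tedge = onsets[k]; snew = 1; }
      else             { tedge = offsets[k]; snew = 0; }
    }
    if (t[i] < tedge) {
      out[i] = prop(tcur, t[i], state);
      ++i;
    } else {
      state = prop(tcur, tedge, state);
      tcur = tedge;
      s = snew;
      ++ei;
    }
  }
  return out;
}
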