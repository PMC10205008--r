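#include <Rcpp.h>
using namespace Rcpp;

static inline double refl(double a) { return a <= 180.0 ? a : 360.0 - a; }

// Turn detection on angular-speed traces. Supra-threshold runs form event
// cores; with extend = true each core is widened outward to the enclosing
// angular-speed valley (frames with strictly decreasing, non-zero |omega|),
// so that the sub-threshold shoulders of a smooth turn profile are kept with
// the event. The minimum-duration rule is applied to the (extended) event;
// failing events are absorbed into the surrounding fixation time.
// theta may have zero columns, in which case directions are reported as NA.
// [[Rcpp::export]]
DataFrame cpp_detect_turns(NumericMatrix omega, NumericMatrix theta,
                           double dt, double threshold, double min_dur,
                           bool extend) {
  const int n = omega.nrow(), na = omega.ncol();
  const bool have_theta = theta.ncol() == na && theta.nrow() == n;
  std::vector<int> agent, s_out, e_out, up_out;
  std::vector<double> dur_out, spd_out, dth_out, th_out;

  for (int a = 0; a < na; ++a) {
    int last_e = -1;  // last frame used by an accepted or candidate event
    int i = 0;
    while (i < n) {
      if (std::fabs(omega(i, a)) < threshold) { ++i; continue; }
      int s = i, e = i;
      while (e + 1 < n && std::fabs(omega(e + 1, a)) >= threshold) ++e;
      i = e + 1;
      if (extend) {
        while (s - 1 > last_e) {
          double w0 = std::fabs(omega(s - 1, a));
          if (w0 <= 0.0 || w0 >= std::fabs(omega(s, a))) break;
          --s;
        }
        while (e + 1 < n) {
          double w1 = std::fabs(omega(e + 1, a));
          if (w1 <= 0.0 || w1 >= std::fabs(omega(e, a))) break;
          ++e;
        }
        i = e + 1;
      }
      last_e = e;
      double dur = (e - s + 1) * dt;
      if (dur < min_dur - 1e-9) continue;
      double msp = 0.0;
      for (int j = s; j <= e; ++j) msp += std::fabs(omega(j, a));
      msp /= (e - s + 1);
      int up = NA_INTEGER;
      double dth = NA_REAL, th_s = NA_REAL;
      if (have_theta) {
        th_s = theta(s, a);
        double th0 = refl(th_s);
        double th1 = refl(theta(e + 1 < n ? e + 1 : e, a));
        dth = th1 - th0;
        up = dth > 0 ? 1 : 0;
      }
      agent.push_back(a + 1);
      s_out.push_back(s + 1);
      e_out.push_back(e + 1);
      dur_out.push_back(dur);
      spd_out.push_back(msp);
      up_out.push_back(up);
      dth_out.push_back(dth);
      th_out.push_back(th_s);
    }
  }
  return DataFrame::create(
      _["agent"] = agent, _["start_frame"] = s_out, _["end_frame"] = e_out,
      _["duration"] = dur_out, _["mean_speed"] = spd_out,
      _["upwind"] = up_out, _["d_reflected"] = dth_out,
      _["theta_start"] = th_out);
}
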