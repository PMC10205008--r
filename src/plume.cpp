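#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-packet plume: packets released from the source at a Poisson rate,
// advected downwind at vd, dispersed crosswind by a telegraph velocity
// (+/- vc switching at Poisson rate lambda_c), growing by sigma^2(age) =
// sigma0^2 + growth * age with mass conservation (peak ~ 1/sigma^2).
// Packet states are tabulated at every sample step in CSR layout.
// [[Rcpp::export]]
List cpp_simulate_plume(double T_total, double warmup, double dt,
                        double release_rate, double vd, double vc,
                        double lambda_c, double sigma0sq, double growth,
                        double c0, double src_x, double src_y,
                        double xmax_cull, double ymax_cull,
                        double peak_floor) {
  const int n_steps = (int)std::round(T_total / dt);
  std::vector<int> step_v;
  std::vector<double> x_v, y_v, s2_v, pk_v;

  double trel = -warmup;
  while (true) {
    trel += exp_rand() / release_rate;
    if (trel >= T_total) break;
    // telegraph crosswind walk from release
    double y = src_y;
    double v = (unif_rand() < 0.5 ? vc : -vc);
    double t_switch = trel + exp_rand() / lambda_c;
    int i0 = (int)std::ceil(std::max(trel, 0.0) / dt - 1e-9);
    // advance y from trel to the first sampled step
    double tcur = trel;
    for (int i = i0; i < n_steps; ++i) {
      double tnext = i * dt;
      while (t_switch < tnext) {
        y += v * (t_switch - tcur);
        tcur = t_switch;
        v = -v;
        t_switch = tcur + exp_rand() / lambda_c;
      }
      y += v * (tnext - tcur);
      tcur = tnext;
      double age = tnext - trel;
      double x = src_x + vd * age;
      double s2 = sigma0sq + growth * age;
      double pk = c0 * sigma0sq / s2;
      if (x > xmax_cull || std::fabs(y) > ymax_cull || pk < peak_floor) break;
      step_v.push_back(i);
      x_v.push_back(x);
      y_v.push_back(y);
      s2_v.push_back(s2);
      pk_v.push_back(pk);
    }
  }

  // counting sort into step-major CSR layout
  const int nrow = step_v.size();
  IntegerVector offsets(n_steps + 1);
  for (int r = 0; r < nrow; ++r) offsets[step_v[r] + 1]++;
  for (int i = 0; i < n_steps; ++i) offsets[i + 1] += offsets[i];
  NumericVector X(nrow), Y(nrow), S2(nrow), PK(nrow), RC(nrow);
  std::vector<int> cur(n_steps, 0);
  for (int r = 0; r < nrow; ++r) {
    int i = step_v[r];
    int pos = offsets[i] + cur[i]++;
    X[pos] = x_v[r];
    Y[pos] = y_v[r];
    S2[pos] = s2_v[r];
    PK[pos] = pk_v[r];
    double a = 2.0 * s2_v[r] * std::log(pk_v[r] / 1e-4);
    RC[pos] = a > 0 ? std::sqrt(a) : 0.0;
  }
  return List::create(_["offsets"] = offsets, _["x"] = X, _["y"] = Y,
                      _["sig2"] = S2, _["peak"] = PK, _["rcut"] = RC,
                      _["n_steps"] = n_steps, _["dt"] = dt);
}

static inline double wrap360(double a) {
  a = std::fmod(a, 360.0);
  if (a < 0) a += 360.0;
  return a;
}

// signed smallest angular difference a - b in (-180, 180]
static inline double ang_diff(double a, double b) {
  double d = std::fmod(a - b, 360.0);
  if (d > 180.0) d -= 360.0;
  if (d <= -180.0) d += 360.0;
  return d;
}

static inline double upwind_sign(double theta) {
  if (theta > 0.0 && theta < 180.0) return 1.0;
  if (theta > 180.0 && theta < 360.0) return -1.0;
  return unif_rand() < 0.5 ? 1.0 : -1.0;
}

// Concentration in the left/right halves of the bilateral elliptical sensor.
static void sensor_conc(const int *offsets, const double *px, const double *py,
                        const double *s2, const double *pk, const double *rc,
                        int step, double x, double y, double hx, double hy,
                        const NumericVector &sa, const NumericVector &sb,
                        const IntegerVector &side, int nL, int nR, double &CL,
                        double &CR) {
  CL = 0.0;
  CR = 0.0;
  const int np = sa.size();
  double lx = -hy, ly = hx;  // unit vector to the agent's left
  for (int j = offsets[step]; j < offsets[step + 1]; ++j) {
    double dx = x - px[j], dy = y - py[j];
    double lim = rc[j] + 1.0;
    if (dx * dx + dy * dy > lim * lim) continue;
    double inv2s2 = 0.5 / s2[j];
    for (int p = 0; p < np; ++p) {
      double qx = x + sb[p] * hx + sa[p] * lx - px[j];
      double qy = y + sb[p] * hy + sa[p] * ly - py[j];
      double c = pk[j] * std::exp(-(qx * qx + qy * qy) * inv2s2);
      if (side[p] > 0) CL += c; else CR += c;
    }
  }
  CL /= nL;
  CR /= nR;
}

// Agent-based navigation in the packet plume. Agents run the turning model
// driven by their own binarized odor signal; when a turn is initiated while
// the Hassenstein-Reichardt motion signal exceeds threshold, the rotation
// sign is chosen toward the vector sum of the upwind and against-motion
// directions instead of being drawn from the upwind-bias sigmoid.
// ablate_rate / ablate_speed replace the novelty response in the respective
// channel by the supplied population-average trace nbar.
// par packs: lambda0..2, mu0..2, tau_dur, min_dur, min_speed, a0, g, tau_g,
// tau_d, tau_n, tau_nd, tau_fast, tau_slow. succ_box: x0, x1, y0, y1.
// [[Rcpp::export]]
List cpp_navigate(List plume, int n_steps, double dt, NumericVector x0,
                  NumericVector y0, NumericVector theta0, double speed,
                  NumericVector par, double det_thr, double motion_thr,
                  bool motion_enabled, bool ablate_rate, bool ablate_speed,
                  NumericVector nbar, NumericVector sa, NumericVector sb,
                  IntegerVector side, NumericVector succ_box,
                  bool collect_nbar) {
  const int na = x0.size();
  const double l0 = par[0], l1 = par[1], l2 = par[2];
  const double m0 = par[3], m1 = par[4], m2 = par[5];
  const double tau_dur = par[6], min_dur = par[7], min_speed = par[8];
  const double a0 = par[9], g = par[10], tau_g = par[11], tau_d = par[12];
  const double tau_n = par[13], tau_nd = par[14];
  const double tau_f = par[15], tau_s = par[16];
  const double ef = std::exp(-dt / tau_f), es = std::exp(-dt / tau_s);
  const double eg = tau_g > 0 ? std::exp(-dt / tau_g) : 0.0;
  const double ed = tau_d > 0 ? std::exp(-dt / tau_d) : 0.0;
  const bool have_plume = plume.size() > 0;
  IntegerVector pl_off;
  NumericVector pl_x, pl_y, pl_s2, pl_pk, pl_rc;
  const int *p_off = nullptr;
  const double *p_x = nullptr, *p_y = nullptr, *p_s2 = nullptr,
               *p_pk = nullptr, *p_rc = nullptr;
  if (have_plume) {
    pl_off = plume["offsets"];
    pl_x = plume["x"];
    pl_y = plume["y"];
    pl_s2 = plume["sig2"];
    pl_pk = plume["peak"];
    pl_rc = plume["rcut"];
    if (pl_off.size() < n_steps + 1) stop("plume shorter than n_steps");
    p_off = pl_off.begin();
    p_x = pl_x.begin();
    p_y = pl_y.begin();
    p_s2 = pl_s2.begin();
    p_pk = pl_pk.begin();
    p_rc = pl_rc.begin();
  }
  const bool use_nbar = (ablate_rate || ablate_speed);
  if (use_nbar && (int)nbar.size() != n_steps)
    stop("nbar trace of length n_steps required for ablation");
  int nL = 0, nR = 0;
  for (int p = 0; p < side.size(); ++p) (side[p] > 0 ? nL : nR)++;

  std::vector<double> x(na), y(na), th(na), Ifast(na, 0), Islow(na, 0),
      Rk(na, 0), t_last(na, -1), gap_amp(na, 0), CLp(na, 0), CRp(na, 0),
      dcur(na, 0), mucur(na, 0), sgn(na, 0);
  std::vector<int> lastS(na, 0), rem(na, 0), done(na, 0), succ(na, 0),
      onsets(na, 0);
  for (int a = 0; a < na; ++a) {
    x[a] = x0[a];
    y[a] = y0[a];
    th[a] = wrap360(theta0[a]);
  }
  NumericVector nbar_out(collect_nbar ? n_steps : 0);

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    for (int a = 0; a < na; ++a) {
      double CL = 0, CR = 0;
      if (have_plume) {
        double hx = std::cos(th[a] * M_PI / 180.0);
        double hy = std::sin(th[a] * M_PI / 180.0);
        sensor_conc(p_off, p_x, p_y, p_s2, p_pk, p_rc, i, x[a], y[a], hx, hy,
                    sa, sb, side, nL, nR, CL, CR);
      }
      int S = ((CL + CR) / 2.0 >= det_thr) ? 1 : 0;
      // novelty bookkeeping: onset when S goes 0 -> 1
      if (S && !lastS[a]) {
        gap_amp[a] = (t_last[a] < 0)
                         ? 1.0
                         : 1.0 - std::exp(-(t - t_last[a]) / tau_n);
        t_last[a] = t;
        onsets[a]++;
      }
      double N = (t_last[a] >= 0)
                     ? gap_amp[a] * std::exp(-(t - t_last[a]) / tau_nd)
                     : 0.0;
      double OFF = Islow[a] - Ifast[a];
      if (OFF < 0) OFF = 0;
      if (collect_nbar) nbar_out[i] += N;

      bool turning = rem[a] > 0;
      if (!turning) {
        double Nr = ablate_rate ? nbar[i] : N;
        double lam = l0 + l1 * Nr + l2 * OFF;
        if (lam < 0) stop("negative turn rate in navigation");
        if (unif_rand() < 1.0 - std::exp(-lam * dt)) {
          double Ns = ablate_speed ? nbar[i] : N;
          double mu = m0 + m1 * Ns + m2 * OFF;
          if (mu <= 0) stop("non-positive excess turn speed in navigation");
          dcur[a] = min_dur + exp_rand() * tau_dur;
          mucur[a] = min_speed + R::rgamma(2.0, mu / 2.0);
          double m = CLp[a] * CR - CL * CRp[a];  // HRC motion signal
          bool used_motion = false;
          if (motion_enabled && std::fabs(m) > motion_thr) {
            // against-motion: +90 deg if motion from the left, else -90
            double am = th[a] + (m > 0 ? 90.0 : -90.0);
            double ux = std::cos(M_PI) + std::cos(am * M_PI / 180.0);
            double uy = std::sin(M_PI) + std::sin(am * M_PI / 180.0);
            if (ux != 0.0 || uy != 0.0) {
              double target = wrap360(std::atan2(uy, ux) * 180.0 / M_PI);
              double d = ang_diff(target, th[a]);
              sgn[a] = (d > 1e-9) ? 1.0
                       : (d < -1e-9 ? -1.0
                                    : (unif_rand() < 0.5 ? 1.0 : -1.0));
              used_motion = true;
            }
          }
          if (!used_motion) {
            double sin2 = std::sin(th[a] * M_PI / 180.0);
            sin2 *= sin2;
            double u = g > 0 ? Rk[a] : 0.0;
            double b = 1.0 / (1.0 + std::exp(-(a0 + g * u) * sin2));
            bool up = unif_rand() < b;
            sgn[a] = upwind_sign(th[a]) * (up ? 1.0 : -1.0);
          }
          rem[a] = (int)std::ceil(dcur[a] / dt - 0.5);
          if (rem[a] < 1) rem[a] = 1;
          done[a] = 0;
          turning = true;
        }
      }
      double w = 0.0;
      if (turning) {
        double tr = (done[a] + 0.5) * dt;
        w = sgn[a] * 6.0 * mucur[a] / (dcur[a] * dcur[a]) * tr * (dcur[a] - tr);
        ++done[a];
        --rem[a];
      }
      // translate at constant ground speed along current heading, then rotate
      double rad = th[a] * M_PI / 180.0;
      x[a] += speed * std::cos(rad) * dt;
      y[a] += speed * std::sin(rad) * dt;
      th[a] = wrap360(th[a] + w * dt);
      if (!succ[a] && x[a] >= succ_box[0] && x[a] <= succ_box[1] &&
          y[a] >= succ_box[2] && y[a] <= succ_box[3])
        succ[a] = 1;
      // end-of-frame kernel state updates with this frame's signal
      Ifast[a] = S + (Ifast[a] - S) * ef;
      Islow[a] = S + (Islow[a] - S) * es;
      Rk[a] = S ? 1.0 + (Rk[a] - 1.0) * eg : Rk[a] * ed;
      CLp[a] = CL;
      CRp[a] = CR;
      lastS[a] = S;
    }
    if (collect_nbar) nbar_out[i] /= na;
  }
  return List::create(_["success"] = wrap(succ), _["x"] = wrap(x),
                      _["y"] = wrap(y), _["n_onsets"] = wrap(onsets),
                      _["nbar"] = nbar_out);
}

// Single-pose bilateral concentration readout (test access to the same
// code path cpp_navigate uses).
// [[Rcpp::export]]
NumericVector cpp_sensor_conc(List plume, int step, double x, double y,
                              double theta_deg, NumericVector sa,
                              NumericVector sb, IntegerVector side) {
  IntegerVector off = plume["offsets"];
  NumericVector px = plume["x"], py = plume["y"], s2 = plume["sig2"],
                pk = plume["peak"], rc = plume["rcut"];
  int nL = 0, nR = 0;
  for (int p = 0; p < side.size(); ++p) (side[p] > 0 ? nL : nR)++;
  double CL, CR;
  double hx = std::cos(theta_deg * M_PI / 180.0);
  double hy = std::sin(theta_deg * M_PI / 180.0);
  sensor_conc(off.begin(), px.begin(), py.begin(), s2.begin(), pk.begin(),
              rc.begin(), step, x, y, hx, hy, sa, sb, side, nL, nR, CL, CR);
  return NumericVector::create(_["C_L"] = CL, _["C_R"] = CR);
}

// Threshold-crossing counts of point concentration at fixed probe locations,
// used for plume-average encounter-frequency estimates.
// [[Rcpp::export]]
IntegerVector cpp_probe_crossings(List plume, NumericVector probe_x,
                                  NumericVector probe_y, double threshold,
                                  int step0) {
  const IntegerVector offsets = plume["offsets"];
  const NumericVector px = plume["x"], py = plume["y"], s2 = plume["sig2"],
                      pk = plume["peak"], rc = plume["rcut"];
  const int n_steps = as<int>(plume["n_steps"]);
  const int np = probe_x.size();
  IntegerVector cross(np);
  std::vector<char> above(np, 0);
  for (int i = step0; i < n_steps; ++i) {
    for (int q = 0; q < np; ++q) {
      double c = 0.0;
      for (int j = offsets[i]; j < offsets[i + 1]; ++j) {
        double dx = probe_x[q] - px[j], dy = probe_y[q] - py[j];
        double d2 = dx * dx + dy * dy;
        if (d2 > rc[j] * rc[j]) continue;
        c += pk[j] * std::exp(-0.5 * d2 / s2[j]);
      }
      char ab = c >= threshold ? 1 : 0;
      if (ab && !above[q]) cross[q]++;
      above[q] = ab;
    }
  }
  return cross;
}
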