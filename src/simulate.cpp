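#include <Rcpp.h>
using namespace Rcpp;

// Shared turn-kinematics helpers ------------------------------------------

static inline double wrap360(double a) {
  a = std::fmod(a, 360.0);
  if (a < 0) a += 360.0;
  return a;
}

static inline double reflect(double a) { return a <= 180.0 ? a : 360.0 - a; }

// +1 if increasing theta moves the heading toward upwind (180 deg), -1
// otherwise; exactly up/downwind gets a random sign.
static inline double upwind_sign(double theta) {
  if (theta > 0.0 && theta < 180.0) return 1.0;
  if (theta > 180.0 && theta < 360.0) return -1.0;
  return unif_rand() < 0.5 ? 1.0 : -1.0;
}

// Simulate a population of agents executing the turning model against shared
// per-frame traces of turn rate lambda (1/s), excess mean turn speed mu
// (deg/s) and bias-kernel output u. Turns are initiated from the non-turning
// state with per-frame probability 1 - exp(-lambda*dt); a turn's angular
// speed follows a parabolic profile sampled at frame midpoints.
// [[Rcpp::export]]
List cpp_simulate_population(NumericVector lambda, NumericVector mu,
                             NumericVector u, double a0, double g,
                             double dt, int n_agents, NumericVector theta0,
                             double tau_dur, double min_dur, double min_speed,
                             bool store_traces, bool mean_orient_only) {
  const int n = lambda.size();
  if (mu.size() != n || u.size() != n) stop("trace length mismatch");
  if ((int)theta0.size() != n_agents) stop("theta0 length != n_agents");
  for (int i = 0; i < n; ++i) {
    if (lambda[i] < 0) stop("negative turn rate lambda(t); check parameters");
    if (mu[i] <= 0) stop("non-positive excess mean turn speed mu(t)");
  }

  NumericMatrix theta_m, omega_m;
  IntegerMatrix turning_m;
  NumericVector orient_sum(mean_orient_only ? n : 0);
  if (store_traces) {
    theta_m = NumericMatrix(n, n_agents);
    omega_m = NumericMatrix(n, n_agents);
    turning_m = IntegerMatrix(n, n_agents);
  }

  std::vector<int> ev_agent, ev_start, ev_nframes, ev_up;
  std::vector<double> ev_dur, ev_speed, ev_theta;

  NumericVector pinit(n);
  for (int i = 0; i < n; ++i) pinit[i] = 1.0 - std::exp(-lambda[i] * dt);

  for (int a = 0; a < n_agents; ++a) {
    double theta = wrap360(theta0[a]);
    int rem = 0, done = 0;
    double d = 0, mu_tot = 0, sgn = 0, tstart = 0;
    for (int i = 0; i < n; ++i) {
      double w = 0.0;
      bool turning = rem > 0;
      if (!turning) {
        if (unif_rand() < pinit[i]) {
          d = min_dur + exp_rand() * tau_dur;
          mu_tot = min_speed + R::rgamma(2.0, mu[i] / 2.0);
          double sin2 = std::sin(theta * M_PI / 180.0);
          sin2 *= sin2;
          double b = 1.0 / (1.0 + std::exp(-(a0 + g * u[i]) * sin2));
          bool up = unif_rand() < b;
          sgn = upwind_sign(theta) * (up ? 1.0 : -1.0);
          rem = (int)std::ceil(d / dt - 0.5);
          if (rem < 1) rem = 1;
          done = 0;
          tstart = 0.0;
          ev_agent.push_back(a + 1);
          ev_start.push_back(i + 1);
          ev_nframes.push_back(rem);
          ev_dur.push_back(d);
          ev_speed.push_back(mu_tot);
          ev_up.push_back(up ? 1 : 0);
          ev_theta.push_back(theta);
          turning = true;
        }
      }
      if (turning) {
        double tr = (done + 0.5) * dt;  // midpoint within the turn
        w = sgn * 6.0 * mu_tot / (d * d) * tr * (d - tr);
        ++done;
        --rem;
      }
      if (store_traces) {
        theta_m(i, a) = theta;
        omega_m(i, a) = w;
        turning_m(i, a) = turning ? 1 : 0;
      }
      if (mean_orient_only) orient_sum[i] += reflect(theta);
      theta = wrap360(theta + w * dt);
    }
  }

  List out = List::create(
      _["events"] = DataFrame::create(
          _["agent"] = ev_agent, _["start_frame"] = ev_start,
          _["n_frames"] = ev_nframes, _["duration"] = ev_dur,
          _["mean_speed"] = ev_speed, _["upwind"] = ev_up,
          _["theta_start"] = ev_theta));
  if (store_traces) {
    out["theta"] = theta_m;
    out["omega"] = omega_m;
    out["turning"] = turning_m;
  }
  if (mean_orient_only) {
    for (int i = 0; i < n; ++i) orient_sum[i] /= n_agents;
    out["mean_orientation"] = orient_sum;
  }
  return out;
}
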