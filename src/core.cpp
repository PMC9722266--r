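#include <Rcpp.h>
using namespace Rcpp;

// Two-state error-driven learner.
// f: environment viscosity normalized to 1 at full strength, one entry per
// reaching trial.  On channel trials the kinematic error is clamped by the
// channel, so the update uses e = 0 (retention only) while the net state is
// still observable as the learning index.
// [[Rcpp::export(name = ".two_state_sim_cpp")]]
List two_state_sim_cpp(double Af, double As, double Bf, double Bs,
                       NumericVector f, LogicalVector is_channel,
                       double xf0, double xs0) {
  int n = f.size();
  NumericVector x(n), e(n), xf(n), xs(n);
  double cf = xf0, cs = xs0;
  for (int i = 0; i < n; ++i) {
    xf[i] = cf; xs[i] = cs;
    double xi = cf + cs;
    x[i] = xi;
    double err = is_channel[i] ? 0.0 : (f[i] - xi);
    e[i] = f[i] - xi;
    cf = Af * cf + Bf * err;
    cs = As * cs + Bs * err;
  }
  return List::create(_["x"] = x, _["e"] = e, _["xf"] = xf, _["xs"] = xs);
}

// Sum of squared residuals of the two-state prediction against observations
// at a subset of trials (NA observations skipped).  Hot loop of the fitter.
// [[Rcpp::export(name = ".two_state_sse_cpp")]]
double two_state_sse_cpp(double Af, double As, double Bf, double Bs,
                         NumericVector f, LogicalVector is_channel,
                         NumericVector obs) {
  int n = f.size();
  double cf = 0.0, cs = 0.0, sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = cf + cs;
    if (!NumericVector::is_na(obs[i])) {
      double r = obs[i] - xi;
      sse += r * r;
    }
    double err = is_channel[i] ? 0.0 : (f[i] - xi);
    cf = Af * cf + Bf * err;
    cs = As * cs + Bs * err;
  }
  return sse;
}

// Lateral point-mass dynamics of one reach, RK4 at a substep resolution.
// vy_half: forward velocity sampled at dt/(2*nsub) resolution,
//          length 2*nsub*(n-1)+1 where n is the number of output samples.
// noise:   force noise per output sample (zero-order hold).
// B:       curl viscosity (0 on channel trials); comp: learner feedforward
//          viscosity estimate; the feedforward command is -comp*vy.
// Returns lateral position/velocity at the n output samples plus the force
// applied by the environment to the hand (curl field, or channel wall).
// [[Rcpp::export(name = ".lateral_reach_cpp")]]
List lateral_reach_cpp(NumericVector vy_half, int n, int nsub, double dt,
                       double mass, double B, double comp,
                       bool channel, double k_ch, double b_ch,
                       double Kp, double Kd, NumericVector noise) {
  NumericVector x(n), vx(n), fenv(n);
  double dtf = dt / nsub;
  double xs = 0.0, vs = 0.0;
  x[0] = 0.0; vx[0] = 0.0;
  fenv[0] = channel ? 0.0 : B * vy_half[0];
  for (int i = 0; i < n - 1; ++i) {
    double Fn = noise[i];
    for (int s = 0; s < nsub; ++s) {
      int base = 2 * (i * nsub + s);
      double vy0 = vy_half[base], vym = vy_half[base + 1], vy1 = vy_half[base + 2];
      // acceleration as a function of (x, v, vy)
      auto acc = [&](double xx, double vv, double vy) {
        double F = -comp * vy - Kp * xx - Kd * vv + Fn;
        if (channel) F += -k_ch * xx - b_ch * vv;
        else F += B * vy;
        return F / mass;
      };
      double k1x = vs,                         k1v = acc(xs, vs, vy0);
      double k2x = vs + 0.5 * dtf * k1v,       k2v = acc(xs + 0.5 * dtf * k1x, vs + 0.5 * dtf * k1v, vym);
      double k3x = vs + 0.5 * dtf * k2v,       k3v = acc(xs + 0.5 * dtf * k2x, vs + 0.5 * dtf * k2v, vym);
      double k4x = vs + dtf * k3v,             k4v = acc(xs + dtf * k3x, vs + dtf * k3v, vy1);
      xs += dtf / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
      vs += dtf / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
    }
    x[i + 1] = xs; vx[i + 1] = vs;
    double vy_here = vy_half[2 * (i + 1) * nsub];
    fenv[i + 1] = channel ? (-k_ch * xs - b_ch * vs) : B * vy_here;
  }
  return List::create(_["x"] = x, _["vx"] = vx, _["f_env"] = fenv);
}

// Max |cluster mass| per row of a t-statistic matrix: clusters are maximal
// runs of same-sign values with |t| > thresh; mass = sum of t in the run.
// [[Rcpp::export(name = ".max_cluster_mass_cpp")]]
NumericVector max_cluster_mass_cpp(NumericMatrix T, double thresh) {
  int nr = T.nrow(), nc = T.ncol();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    double best = 0.0, cur = 0.0;
    int sign = 0;
    for (int c = 0; c < nc; ++c) {
      double t = T(r, c);
      int s = (t > thresh) ? 1 : ((t < -thresh) ? -1 : 0);
      if (s != 0 && s == sign) {
        cur += t;
      } else {
        if (std::abs(cur) > best) best = std::abs(cur);
        cur = (s != 0) ? t : 0.0;
      }
      sign = s;
    }
    if (std::abs(cur) > best) best = std::abs(cur);
    out[r] = best;
  }
  return out;
}
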