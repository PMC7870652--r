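// Stochastic and ODE kernels for tip-link kinetics.
//
// All forces in pN, times in s, concentrations in M.  Random draws use R's
// RNG (RNGScope), so results are reproducible with set.seed() from R.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double step_prob(double rate, double dt) {
  double x = rate * dt;
  // exact Bernoulli probability when x is not small; linearization otherwise
  return (x > 1e-3) ? -std::expm1(-x) : x;
}

struct DimerRates {
  double k_off0, f_beta, k_on, C_eff0, f_c;
  int variant;      // 0 = full, 1 = constant_ceff, 2 = no_rebinding
  bool share_load;  // if false, both off-rates carry the full-force exponent

  inline double k1(double F) const { return k_off0 * std::exp(F / f_beta); }
  inline double k2(double F) const {
    return share_load ? k_off0 * std::exp(F / (2.0 * f_beta)) : k1(F);
  }
  inline double rebind(double F) const {
    switch (variant) {
      case 0: { double z = F / f_c; return C_eff0 * std::exp(-z * z) * k_on; }
      case 1: return C_eff0 * k_on;
      default: return 0.0;
    }
  }
};

} // namespace

// Survival of the homogeneous chain B2 <-> B1 -> U under linear loading
// F = l_r * t, integrated with classic RK4 and a rate-limited adaptive step.
// Returns the full trajectory: time, B2, B1 and the rupture density k1*B1.
// [[Rcpp::export]]
List ode_rupture_cpp(double l_r, double k_off0, double f_beta, double k_on,
                     double C_eff0, double f_c, int variant, bool share_load,
                     double eps = 0.02, double s_min = 1e-7,
                     double max_steps = 1e8) {
  DimerRates rr{k_off0, f_beta, k_on, C_eff0, f_c, variant, share_load};
  std::vector<double> tv, b2v, b1v, dv;
  tv.reserve(4096); b2v.reserve(4096); b1v.reserve(4096); dv.reserve(4096);

  double t = 0.0, B2 = 1.0, B1 = 0.0;
  tv.push_back(t); b2v.push_back(B2); b1v.push_back(B1); dv.push_back(0.0);

  auto deriv = [&](double tt, double y0, double y1, double &d0, double &d1) {
    double F = l_r * tt;
    double k1 = rr.k1(F), k2 = rr.k2(F), c = rr.rebind(F);
    d0 = c * y1 - 2.0 * k2 * y0;
    d1 = -(c + k1) * y1 + 2.0 * k2 * y0;
  };

  long steps = 0;
  while (B2 + B1 > s_min) {
    if (++steps > (long)max_steps)
      stop("rupture-density integration exceeded the step budget; tolerance not met");
    double F = l_r * t;
    double rtot = rr.k1(F) + 2.0 * rr.k2(F) + rr.rebind(F);
    double dt = eps / std::max(rtot, 1e-12);
    // resolve the exponential force dependence of the rates as well
    double dt_force = f_beta / (20.0 * l_r);
    if (dt > dt_force) dt = dt_force;

    double a0, a1, b0, b1, c0, c1, d0, d1;
    deriv(t, B2, B1, a0, a1);
    deriv(t + dt / 2, B2 + dt / 2 * a0, B1 + dt / 2 * a1, b0, b1);
    deriv(t + dt / 2, B2 + dt / 2 * b0, B1 + dt / 2 * b1, c0, c1);
    deriv(t + dt, B2 + dt * c0, B1 + dt * c1, d0, d1);
    B2 += dt / 6.0 * (a0 + 2 * b0 + 2 * c0 + d0);
    B1 += dt / 6.0 * (a1 + 2 * b1 + 2 * c1 + d1);
    if (B2 < 0) B2 = 0;
    if (B1 < 0) B1 = 0;
    t += dt;
    tv.push_back(t); b2v.push_back(B2); b1v.push_back(B1);
    dv.push_back(rr.k1(l_r * t) * B1);
  }

  return List::create(_["time"] = wrap(tv), _["B2"] = wrap(b2v),
                      _["B1"] = wrap(b1v), _["density"] = wrap(dv));
}

namespace {

// 3x3 solve by Cramer's rule
inline void solve3(const double M[3][3], const double b[3], double x[3]) {
  double det =
      M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
      M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
      M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  double inv = 1.0 / det;
  x[0] = inv * (b[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                M[0][1] * (b[1] * M[2][2] - M[1][2] * b[2]) +
                M[0][2] * (b[1] * M[2][1] - M[1][1] * b[2]));
  x[1] = inv * (M[0][0] * (b[1] * M[2][2] - M[1][2] * b[2]) -
                b[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                M[0][2] * (M[1][0] * b[2] - b[1] * M[2][0]));
  x[2] = inv * (M[0][0] * (M[1][1] * b[2] - b[1] * M[2][1]) -
                M[0][1] * (M[1][0] * b[2] - b[1] * M[2][0]) +
                b[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]));
}

} // namespace

// Heterogeneous chain B2 <-> {B12, B11} -> U under linear loading.
// Bond type 1 holds the load in B11, type 2 in B12; k_ij uses exponent
// F / (i * f_beta_j).  Rebinding into B2 uses the partner's on-rate and a
// shared zero-force effective concentration with per-type compliance force
// scales.  The mutant off-rate can exceed the surviving time scales by many
// orders of magnitude once only one strand remains bound, so the linear
// system is integrated with the L-stable TR-BDF2 scheme (stiffly accurate;
// step size set by accuracy on the occupied states).
// [[Rcpp::export]]
List ode_rupture_het_cpp(double l_r,
                         double k_off0_1, double f_beta_1,
                         double k_off0_2, double f_beta_2,
                         double k_on1, double k_on2, double C0,
                         double f_c1, double f_c2,
                         double eps = 0.02, double s_min = 1e-7,
                         double max_steps = 2e7) {
  std::vector<double> tv, b2v, b12v, b11v, dv;
  double t = 0.0;
  double y[3] = {1.0, 0.0, 0.0};  // B2, B12, B11
  tv.push_back(0); b2v.push_back(1); b12v.push_back(0); b11v.push_back(0);
  dv.push_back(0);

  struct Rates { double k21, k22, k11, k12, c1on2, c2on1; };
  auto rates_at = [&](double F) {
    Rates r;
    // exponents capped: rates beyond exp(80) are instantaneous on every
    // time scale here and would overflow the 3x3 determinants otherwise
    r.k21 = k_off0_1 * std::exp(std::min(F / (2.0 * f_beta_1), 80.0));
    r.k22 = k_off0_2 * std::exp(std::min(F / (2.0 * f_beta_2), 80.0));
    r.k11 = k_off0_1 * std::exp(std::min(F / f_beta_1, 80.0));
    r.k12 = k_off0_2 * std::exp(std::min(F / f_beta_2, 80.0));
    double z1 = F / f_c1, z2 = F / f_c2;
    r.c1on2 = C0 * std::exp(-z1 * z1) * k_on2;  // rebinding out of B11
    r.c2on1 = C0 * std::exp(-z2 * z2) * k_on1;  // rebinding out of B12
    return r;
  };
  auto fillA = [](const Rates &r, double A[3][3]) {
    A[0][0] = -(r.k21 + r.k22); A[0][1] = r.c2on1; A[0][2] = r.c1on2;
    A[1][0] = r.k21; A[1][1] = -(r.c2on1 + r.k12); A[1][2] = 0.0;
    A[2][0] = r.k22; A[2][1] = 0.0; A[2][2] = -(r.c1on2 + r.k11);
  };

  const double g = 2.0 - std::sqrt(2.0);  // TR-BDF2 gamma
  double fb_min = std::min(f_beta_1, f_beta_2);
  long steps = 0;
  while (y[0] + y[1] + y[2] > s_min) {
    if (++steps > (long)max_steps)
      stop("rupture-density integration exceeded the step budget; tolerance not met");
    double S = y[0] + y[1] + y[2];
    Rates r0 = rates_at(l_r * t);
    // accuracy-based step: occupancy-weighted outflow over the states
    double r_occ = ((r0.k21 + r0.k22) * y[0] + (r0.c2on1 + r0.k12) * y[1] +
                    (r0.c1on2 + r0.k11) * y[2]) / S;
    double dt = eps / std::max(r_occ, 1e-12);
    double dt_force = fb_min / (40.0 * l_r);
    if (dt > dt_force) dt = dt_force;

    double A0[3][3], Ag[3][3], A1[3][3];
    fillA(r0, A0);
    fillA(rates_at(l_r * (t + g * dt)), Ag);
    fillA(rates_at(l_r * (t + dt)), A1);

    // trapezoidal stage over [t, t + g*dt]
    double rhs[3], M[3][3], ys[3];
    for (int i = 0; i < 3; ++i) {
      rhs[i] = y[i];
      for (int j = 0; j < 3; ++j) {
        rhs[i] += (g * dt / 2.0) * A0[i][j] * y[j];
        M[i][j] = ((i == j) ? 1.0 : 0.0) - (g * dt / 2.0) * Ag[i][j];
      }
    }
    solve3(M, rhs, ys);
    // BDF2 stage to t + dt
    double c1 = 1.0 / (g * (2.0 - g));
    double c2 = (1.0 - g) * (1.0 - g) / (g * (2.0 - g));
    double c3 = (1.0 - g) / (2.0 - g);
    for (int i = 0; i < 3; ++i) {
      rhs[i] = c1 * ys[i] - c2 * y[i];
      for (int j = 0; j < 3; ++j)
        M[i][j] = ((i == j) ? 1.0 : 0.0) - c3 * dt * A1[i][j];
    }
    double yn[3];
    solve3(M, rhs, yn);
    for (int i = 0; i < 3; ++i) y[i] = std::max(yn[i], 0.0);
    t += dt;

    Rates r1 = rates_at(l_r * t);
    tv.push_back(t); b2v.push_back(y[0]); b12v.push_back(y[1]);
    b11v.push_back(y[2]);
    dv.push_back(r1.k11 * y[2] + r1.k12 * y[1]);
  }

  return List::create(_["time"] = wrap(tv), _["B2"] = wrap(b2v),
                      _["B12"] = wrap(b12v), _["B11"] = wrap(b11v),
                      _["density"] = wrap(dv));
}

// First-passage times B2 -> U of the constant-rate chain by exact Gillespie
// simulation: B2 -> B1 at 2*k2, B1 -> B2 at c_on, B1 -> U at k1.
// [[Rcpp::export]]
NumericVector gillespie_constant_cpp(int n, double k1, double k2, double c_on) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int state = 2;
    for (;;) {
      if (state == 2) {
        t += R::rexp(1.0 / (2.0 * k2));
        state = 1;
      } else {
        double rtot = k1 + c_on;
        t += R::rexp(1.0 / rtot);
        if (unif_rand() * rtot < k1) break;  // rupture
        state = 2;
      }
    }
    out[i] = t;
  }
  return out;
}

// Rupture times under linear loading by a fixed-probability stochastic chain
// (per-step Bernoulli transitions with p = 1 - exp(-rate*dt), step size
// rate-limited).  Serves as the stochastic cross-check of the inverse-CDF
// sampler.
// [[Rcpp::export]]
NumericVector step_rupture_cpp(int n, double l_r, double k_off0, double f_beta,
                               double k_on, double C_eff0, double f_c,
                               int variant, bool share_load,
                               double eps = 0.005) {
  RNGScope scope;
  DimerRates rr{k_off0, f_beta, k_on, C_eff0, f_c, variant, share_load};
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int state = 2;
    for (;;) {
      double F = l_r * t;
      double k1 = rr.k1(F), k2 = rr.k2(F), c = rr.rebind(F);
      double rtot = (state == 2) ? 2.0 * k2 : (k1 + c);
      double dt = eps / std::max(rtot, 1e-12);
      double dt_force = f_beta / (40.0 * l_r);
      if (dt > dt_force) dt = dt_force;
      if (unif_rand() < step_prob(rtot, dt)) {
        if (state == 2) {
          state = 1;
        } else if (unif_rand() * (k1 + c) < k1) {
          t += dt;
          break;
        } else {
          state = 2;
        }
      }
      t += dt;
    }
    out[i] = t;
  }
  return out;
}

// Monte Carlo simulation of tip-link lifetime under sinusoidal hair-bundle
// deflection.  Fixed time step dt; per-step Bernoulli transitions over the
// {B2, B1, U} chain with rates evaluated at the instantaneous tip-link
// tension F_t = max(0, F_rest + gamma*k_g*(x - x_a)).  Optional slow
// adaptation moves the motor position x_a (climb decreases x_a at
// climb_nm_s, slipping increases it at slip_coeff * F_t).
// [[Rcpp::export]]
List bundle_mc_cpp(int n_runs, double freq, double amp, NumericVector phase,
                   double k_off0, double f_beta, double k_on, double C_eff0,
                   double f_c,
                   double k_g, double gamma, double F_rest,
                   double climb_nm_s, double slip_coeff, bool adapt,
                   double dt, double t_cap, bool record_events = false,
                   double burn_in = 0.0) {
  RNGScope scope;
  NumericVector life(n_runs);
  LogicalVector capped(n_runs);
  std::vector<double> ev_time;
  std::vector<int> ev_code, ev_run;  // code: 1 = B2->B1, 2 = B1->B2, 3 = B1->U

  const double omega = 2.0 * M_PI * freq;
  const double inv_fb = 1.0 / f_beta, inv_2fb = 0.5 / f_beta;
  const double inv_fc2 = 1.0 / (f_c * f_c);

  for (int i = 0; i < n_runs; ++i) {
    double t = 0.0, x_a = 0.0, ph = phase[i % phase.size()];
    int state = 2;
    bool cap = false;
    if (adapt && burn_in > 0.0) {
      // deterministic motor burn-in: the connection is assumed to form
      // during ongoing stimulation, with the adaptation motor already at
      // its stimulus-adapted steady state
      long nb = (long)std::ceil(burn_in / dt);
      for (long k = 0; k < nb; ++k) {
        double tb = -burn_in + k * dt;
        double xb = (amp > 0.0) ? amp * std::sin(omega * tb + ph) : 0.0;
        double Fb = F_rest + gamma * k_g * (xb - x_a);
        if (Fb < 0) Fb = 0;
        x_a += dt * (slip_coeff * Fb - climb_nm_s);
      }
    }
    for (;;) {
      if (t >= t_cap) { cap = true; break; }
      double x = (amp > 0.0) ? amp * std::sin(omega * t + ph) : 0.0;
      double F = F_rest + gamma * k_g * (x - x_a);
      if (F < 0) F = 0;
      if (state == 2) {
        double r = 2.0 * k_off0 * std::exp(F * inv_2fb);
        if (unif_rand() < step_prob(r, dt)) {
          state = 1;
          if (record_events) { ev_time.push_back(t); ev_code.push_back(1); ev_run.push_back(i + 1); }
        }
      } else {
        double k1 = k_off0 * std::exp(F * inv_fb);
        double c = C_eff0 * std::exp(-F * F * inv_fc2) * k_on;
        double r = k1 + c;
        if (unif_rand() < step_prob(r, dt)) {
          if (unif_rand() * r < k1) {
            if (record_events) { ev_time.push_back(t); ev_code.push_back(3); ev_run.push_back(i + 1); }
            t += dt;
            break;
          }
          state = 2;
          if (record_events) { ev_time.push_back(t); ev_code.push_back(2); ev_run.push_back(i + 1); }
        }
      }
      if (adapt) x_a += dt * (slip_coeff * F - climb_nm_s);
      t += dt;
    }
    life[i] = t;
    capped[i] = cap;
  }

  List out = List::create(_["lifetime"] = life, _["capped"] = capped);
  if (record_events)
    out["events"] = DataFrame::create(_["run"] = wrap(ev_run),
                                      _["time"] = wrap(ev_time),
                                      _["code"] = wrap(ev_code));
  return out;
}
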