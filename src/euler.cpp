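#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step forward Euler integrator for the lysis-circuit population model
// and its variants. States are hard-clamped at zero after every step (substrate
// additionally at one); the cumulative released-load integral and mutant-
// fraction threshold crossings are accumulated on the full-resolution grid.
//
// par layout (fixed order, packed by pack_params() on the R side):
//   0 gamma0, 1 rho_s, 2 alpha0, 3 K, 4 n, 5 beta0, 6 k, 7 m, 8 delta,
//   9 mu, 10 r_s, 11 K_s, 12 d
// model: 0 core, 1 substrate, 2 mutation, 3 dilution
// toxin_dilution: 0 -> (gamma - alpha)+ p, 1 -> (gamma)+ p
// load_integrand: 0 -> (alpha - gamma)+ x, 1 -> alpha x
// Forcing is piecewise constant: level seg_levels[j] applies for
// t < seg_ends[j]. For the dilution model the level is the AHL supply rate
// (nM/h) feeding da/dt = supply - d*a, and beta is evaluated at the state a.

static inline double hill_cpp(double v, double thr, double coef) {
  if (v <= 0.0) return 0.0;
  double r = std::pow(v / thr, coef);
  return r / (1.0 + r);
}

// [[Rcpp::export]]
List euler_engine(NumericVector par, int model, int toxin_dilution,
                  int load_integrand, NumericVector seg_ends,
                  NumericVector seg_levels, double x0, double y0, double p0,
                  double s0, double a0, double t_end, double dt,
                  int save_every, NumericVector thresholds) {
  const double gamma0 = par[0], rho_s = par[1], alpha0 = par[2], K = par[3],
               n = par[4], beta0 = par[5], k = par[6], m = par[7],
               delta = par[8], mu = par[9], r_s = par[10], K_s = par[11],
               d = par[12];

  const R_xlen_t nseg = seg_ends.size();
  const long nst = (long)std::llround(t_end / dt);
  if (nst < 1) stop("t_end must exceed at least one time step");
  const long nsave = nst / save_every + 1 + ((nst % save_every) ? 1 : 0);

  NumericVector out_t(nsave), out_x(nsave), out_y(nsave), out_p(nsave),
      out_s(nsave), out_a(nsave), out_ahl(nsave), out_load(nsave);

  const R_xlen_t nthr = thresholds.size();
  NumericVector tko_time(nthr, NA_REAL), tko_load(nthr, NA_REAL);
  R_xlen_t next_thr = 0;  // thresholds sorted ascending; f is non-decreasing

  double x = x0, y = y0, p = p0, s = s0, a = a0;
  double load = 0.0, prev_rel = 0.0, prev_f = NA_REAL, prev_load = 0.0;
  long clamped = 0;
  R_xlen_t seg = 0;
  long isave = 0;

  for (long i = 0; i <= nst; ++i) {
    const double t = i * dt;
    while (seg < nseg - 1 && t >= seg_ends[seg]) ++seg;
    const double level = seg_levels[seg];

    double growth_factor = 1.0 - (x + y) / rho_s;
    if (model == 1) growth_factor *= s / (K_s + s);
    const double gamma = gamma0 * growth_factor;
    const double alpha = alpha0 * hill_cpp(p, K, n);
    const double ahl_now = (model == 3) ? a : level;
    const double beta = beta0 * hill_cpp(ahl_now, k, m);

    // released-load integrand, trapezoidal on the full grid
    const double rel =
        (load_integrand == 0) ? std::max(alpha - gamma, 0.0) * x : alpha * x;
    if (i > 0) load += 0.5 * (rel + prev_rel) * dt;
    prev_rel = rel;

    const double tot = x + y;
    double f = NA_REAL;
    if (tot > 0.0) f = y / tot;

    // threshold crossings, linearly interpolated inside the step
    if (!ISNA(f)) {
      while (next_thr < nthr && f >= thresholds[next_thr]) {
        double w = 1.0;
        if (!ISNA(prev_f) && f > prev_f)
          w = (thresholds[next_thr] - prev_f) / (f - prev_f);
        if (ISNA(prev_f)) w = 1.0;
        const double t_prev = (i > 0) ? (i - 1) * dt : 0.0;
        tko_time[next_thr] = (i > 0) ? t_prev + w * dt : 0.0;
        tko_load[next_thr] =
            (i > 0) ? prev_load + w * (load - prev_load) : 0.0;
        ++next_thr;
      }
      prev_f = f;
    }
    prev_load = load;

    if (i % save_every == 0 || i == nst) {
      out_t[isave] = t;
      out_x[isave] = x;
      out_y[isave] = y;
      out_p[isave] = p;
      out_s[isave] = s;
      out_a[isave] = a;
      out_ahl[isave] = ahl_now;
      out_load[isave] = load;
      ++isave;
    }

    if (i == nst) break;

    double dx, dy, dp, ds = 0.0, da = 0.0;
    const double dil_rate = (toxin_dilution == 0)
                                ? std::max(gamma - alpha, 0.0)
                                : std::max(gamma, 0.0);
    dx = (gamma - alpha) * x;
    dy = gamma * y;
    dp = beta - dil_rate * p - delta * p;
    if (model == 2) {
      dx -= mu * x;
      dy += mu * x;
    } else if (model == 3) {
      dx -= d * x;
      dy -= d * y;
      da = level - d * a;
    }
    if (model == 1) ds = -r_s * (x + y) * s / (K_s + s);

    x += dt * dx;
    y += dt * dy;
    p += dt * dp;
    s += dt * ds;
    a += dt * da;
    if (x < 0.0) { x = 0.0; ++clamped; }
    if (y < 0.0) { y = 0.0; ++clamped; }
    if (p < 0.0) { p = 0.0; ++clamped; }
    if (s < 0.0) { s = 0.0; ++clamped; }
    if (s > 1.0) { s = 1.0; ++clamped; }
    if (a < 0.0) { a = 0.0; ++clamped; }

    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(p) ||
        !std::isfinite(s) || !std::isfinite(a)) {
      return List::create(_["ok"] = false, _["bad_time"] = t + dt);
    }
  }

  return List::create(
      _["ok"] = true, _["t"] = out_t[Range(0, isave - 1)],
      _["x"] = out_x[Range(0, isave - 1)], _["y"] = out_y[Range(0, isave - 1)],
      _["p"] = out_p[Range(0, isave - 1)], _["s"] = out_s[Range(0, isave - 1)],
      _["a"] = out_a[Range(0, isave - 1)],
      _["ahl"] = out_ahl[Range(0, isave - 1)],
      _["load"] = out_load[Range(0, isave - 1)],
      _["final"] = NumericVector::create(_["x"] = x, _["y"] = y, _["p"] = p,
                                         _["s"] = s, _["a"] = a),
      _["takeover_time"] = tko_time, _["takeover_load"] = tko_load,
      _["final_load"] = load, _["n_clamped"] = (double)clamped);
}
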