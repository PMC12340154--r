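#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal current-to-rate transfer function H(x) = (a x - b) / (1 - exp(-d (a x - b))).
// The singularity at a x = b is removable; a second-order series keeps the
// evaluation smooth through that point.
static inline double transfer_H(double x, double a, double b, double d) {
  double u = a * x - b;
  double t = d * u;
  if (std::fabs(t) < 1e-6) {
    return (1.0 / d) * (1.0 + 0.5 * t + t * t / 12.0);
  }
  return u / (1.0 - std::exp(-t));
}

// [[Rcpp::export]]
NumericVector transfer_H_cpp(NumericVector x, double a, double b, double d) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = transfer_H(x[i], a, b, d);
  return out;
}

// Euler-Maruyama integration of the coupled gating equations with optional
// mean-reverting (Ornstein-Uhlenbeck) couplings on a subset of edges.
//
// Noise draws come from the R RNG so that set.seed() in R gives bit-identical
// trajectories. Draw order per step is fixed: node noises in region order,
// then coupling noises in dynamic-edge order. When `noise` has rows, it is
// used as an externally supplied standard-normal path at a coarser step and
// each coarse draw is reused for `refine` consecutive steps scaled by
// 1/sqrt(refine), preserving the Brownian increments under step halving.
//
// [[Rcpp::export]]
List rww_simulate_cpp(NumericMatrix C, IntegerMatrix dyn_edges,
                      NumericVector eta, NumericVector sigma_c,
                      double a, double b, double d,
                      double w, double G, double J_N, double I_0,
                      double tau_S, double gamma, double sigma_node,
                      double dt, double duration, double burn_in,
                      double record_dt,
                      NumericVector S0, NumericVector C0,
                      NumericMatrix noise, int refine) {
  const int n = C.nrow();
  const int k = dyn_edges.nrow();
  const long total = (long)std::lround(duration / dt);
  const long burn = (long)std::lround(burn_in / dt);
  const long rec_every = std::max(1L, (long)std::lround(record_dt / dt));
  const long n_rec = (total - burn) / rec_every + 1;
  const bool ext_noise = noise.nrow() > 0;
  const double sq = std::sqrt(dt);
  const double rf = ext_noise ? 1.0 / std::sqrt((double)refine) : 1.0;

  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> Ct(C0.begin(), C0.end());
  std::vector<double> Ceff(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Ceff[i * n + j] = C(i, j);

  NumericMatrix S_rec(n_rec, n);
  NumericMatrix C_rec(k > 0 ? n_rec : 0, k);
  NumericVector times(n_rec);
  long clip_count = 0;
  long rec_i = 0;

  for (long s = 0; s <= total; ++s) {
    // record state before stepping so t = burn_in .. duration inclusive
    if (s >= burn && (s - burn) % rec_every == 0 && rec_i < n_rec) {
      times[rec_i] = s * dt;
      for (int i = 0; i < n; ++i) S_rec(rec_i, i) = S[i];
      for (int e = 0; e < k; ++e) C_rec(rec_i, e) = Ct[e];
      ++rec_i;
    }
    if (s == total) break;

    // dynamic couplings enter the input current in place of their means
    for (int e = 0; e < k; ++e)
      Ceff[dyn_edges(e, 0) * n + dyn_edges(e, 1)] = Ct[e];

    long cidx = ext_noise ? (s / refine) : 0;
    int ncol_used = 0;

    for (int i = 0; i < n; ++i) {
      double x = w * J_N * S[i] + I_0;
      for (int j = 0; j < n; ++j) x += G * J_N * Ceff[i * n + j] * S[j];
      double drift = -S[i] / tau_S + (1.0 - S[i]) * gamma * transfer_H(x, a, b, d);
      double xi = ext_noise ? noise(cidx, ncol_used) * rf : R::norm_rand();
      ++ncol_used;
      double Snew = S[i] + drift * dt + sigma_node * sq * xi;
      if (Snew < 0.0) { Snew = 0.0; ++clip_count; }
      else if (Snew > 1.0) { Snew = 1.0; ++clip_count; }
      if (!std::isfinite(Snew)) {
        return List::create(_["diverged"] = true, _["step"] = (double)s,
                            _["region"] = i + 1);
      }
      S[i] = Snew;
    }
    for (int e = 0; e < k; ++e) {
      double cm = C(dyn_edges(e, 0), dyn_edges(e, 1));
      double xi = ext_noise ? noise(cidx, ncol_used) * rf : R::norm_rand();
      ++ncol_used;
      Ct[e] += -eta[e] * (Ct[e] - cm) * dt + sigma_c[e] * sq * xi;
      if (!std::isfinite(Ct[e])) {
        return List::create(_["diverged"] = true, _["step"] = (double)s,
                            _["region"] = NA_INTEGER);
      }
    }
  }

  return List::create(_["diverged"] = false, _["times"] = times,
                      _["S"] = S_rec, _["C"] = C_rec,
                      _["clip_count"] = (double)clip_count);
}

// Balloon-Windkessel hemodynamic model: four states per region
// (vasodilatory signal s, inflow f, volume v, deoxyhemoglobin q),
// driven independently per region by the neural activity z(t).
//
// [[Rcpp::export]]
List balloon_bold_cpp(NumericMatrix z, double dt, double tr,
                      double kappa, double gamma_h, double tau_h,
                      double alpha, double rho, double V0) {
  const int T = z.nrow();
  const int n = z.ncol();
  const long tr_every = std::max(1L, (long)std::lround(tr / dt));
  const long n_out = (T - 1) / tr_every + 1;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ia = 1.0 / alpha;

  NumericMatrix bold(n_out, n);
  NumericVector t_out(n_out);

  for (int r = 0; r < n; ++r) {
    double sv = 0.0, f = 1.0, v = 1.0, q = 1.0;
    long oi = 0;
    for (int t = 0; t < T; ++t) {
      if (t % tr_every == 0 && oi < n_out) {
        bold(oi, r) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        if (r == 0) t_out[oi] = t * dt;
        ++oi;
      }
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double via = std::pow(v, ia);
      double ds = z(t, r) - kappa * sv - gamma_h * (f - 1.0);
      double df = sv;
      double dv = (f - via) / tau_h;
      double dq = (f * E / rho - via * q / v) / tau_h;
      sv += ds * dt; f += df * dt; v += dv * dt; q += dq * dt;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (!std::isfinite(sv) || !std::isfinite(f) ||
          !std::isfinite(v) || !std::isfinite(q)) {
        return List::create(_["diverged"] = true, _["step"] = (double)t,
                            _["region"] = r + 1);
      }
    }
  }
  return List::create(_["diverged"] = false, _["times"] = t_out,
                      _["bold"] = bold);
}
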