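// Fast evaluation of the pharmacodynamic cost: effect-compartment exact
// step on a uniform dense grid, pure delay by linear interpolation, Hill
// law, frequency-curve lookup and the sum-of-squares + weighted
// maximum-absolute-error cost.  Mirrors the R reference path
// (effect_compartment / apply_delay / dopaminergic_input /
// frequency_from_D_series / pd_cost); equivalence is covered by tests.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double interp(const double* x, const double* y, int n, double xi) {
  if (xi <= x[0]) return y[0];
  if (xi >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xi) lo = mid; else hi = mid;
  }
  double w = (xi - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] + w * (y[lo + 1] - y[lo]);
}

} // namespace

// theta = (ke3, T, D0, Dmax, Dc50, ND); c1 on the uniform grid 0, h, 2h, ...
// [[Rcpp::export(name = ".pd_cost_cpp")]]
double pd_cost_cpp(NumericVector theta, NumericVector c1, double h,
                   NumericVector t_obs, NumericVector f_obs,
                   NumericVector curve_D, NumericVector curve_f, double k) {
  const double ke3 = theta[0], T = theta[1], D0 = theta[2],
               Dmax = theta[3], Dc50 = theta[4], ND = theta[5];
  const int n = c1.size();
  std::vector<double> c3(n);
  c3[0] = 0.0;
  const double al = std::exp(-ke3 * h);
  for (int i = 1; i < n; ++i) {
    const double s = (c1[i] - c1[i - 1]) / h;
    c3[i] = c1[i] - s / ke3 + (c3[i - 1] - c1[i - 1] + s / ke3) * al;
  }
  const int m = t_obs.size();
  const int nc = curve_D.size();
  double sse = 0.0, amax = 0.0;
  for (int j = 0; j < m; ++j) {
    const double td = t_obs[j] - T;
    double cd = 0.0;
    if (td > 0) {
      const double pos = td / h;
      const int lo = std::min((int)pos, n - 2);
      cd = c3[lo] + (pos - lo) * (c3[lo + 1] - c3[lo]);
      if (cd < 0) cd = 0;
    }
    const double r = std::pow(cd / Dc50, ND);
    const double D = D0 + Dmax * (R_FINITE(r) ? r / (1.0 + r) : 1.0);
    const double fmod = interp(&curve_D[0], &curve_f[0], nc, D);
    const double res = fmod - f_obs[j];
    sse += res * res;
    if (std::fabs(res) > amax) amax = std::fabs(res);
  }
  return sse + k * amax;
}

namespace {

struct PdObjective {
  const NumericVector& c1;
  double h;
  const NumericVector& t_obs, &f_obs, &curve_D, &curve_f;
  double k;
  const std::vector<double>& lo, &hi;
  const std::vector<double>& prior_c, &prior_w;  // log-space centre, scale
  double prior_lambda;
  mutable int evals = 0;

  // z -> theta: log ke3, softplus T, log D0, log Dmax, (u = ND log Dc50, log ND)
  void theta_from_z(const double* z, double* th) const {
    const double ND = std::exp(z[5]);
    th[0] = std::exp(z[0]);
    th[1] = z[1] > 30 ? z[1] : std::log1p(std::exp(z[1]));
    th[2] = std::exp(z[2]);
    th[3] = std::exp(z[3]);
    th[4] = std::exp(z[4] / ND);
    th[5] = ND;
  }

  double operator()(const double* z) const {
    ++evals;
    double th[6];
    theta_from_z(z, th);
    for (int i = 0; i < 6; ++i) if (!R_FINITE(th[i])) return 1e12;
    if (th[5] > 80 || th[4] > 1e4) return 1e12;
    NumericVector theta(th, th + 6);
    double cost = pd_cost_cpp(theta, const_cast<NumericVector&>(c1), h,
                              const_cast<NumericVector&>(t_obs),
                              const_cast<NumericVector&>(f_obs),
                              const_cast<NumericVector&>(curve_D),
                              const_cast<NumericVector&>(curve_f), k);
    // soft box on the physiological ranges (quadratic in log space; T linear)
    double pen = 0.0;
    for (int i = 0; i < 6; ++i) {
      if (i == 1) {
        const double d = std::max(th[1] - hi[1], 0.0);
        pen += d * d / 100.0;
      } else {
        const double v = std::max(th[i], 1e-12);
        const double dl = std::min(std::log(v / lo[i]), 0.0);
        const double dh = std::max(std::log(v / hi[i]), 0.0);
        pen += dl * dl + dh * dh;
      }
    }
    // weak MAP shrinkage towards the physiological range centres: picks
    // the centre of flat likelihood valleys, negligible where the data
    // constrain the parameter
    double pri = 0.0;
    if (prior_lambda > 0) {
      for (int i = 0; i < 6; ++i) {
        if (prior_w[i] <= 0) continue;
        const double zi = (i == 1) ? th[1] : std::log(std::max(th[i], 1e-12));
        const double d = (zi - prior_c[i]) / prior_w[i];
        pri += d * d;
      }
    }
    return cost + 1e5 * pen + prior_lambda * pri;
  }
};

// standard Nelder-Mead on n = 6 parameters
double nelder_mead(const PdObjective& f, std::vector<double>& x,
                   int maxit, double reltol) {
  const int n = 6;
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  std::vector<std::vector<double>> S(n + 1, x);
  std::vector<double> fv(n + 1);
  for (int i = 1; i <= n; ++i)
    S[i][i - 1] += (std::fabs(S[i][i - 1]) > 0.1 ? 0.1 * S[i][i - 1] : 0.1);
  for (int i = 0; i <= n; ++i) fv[i] = f(S[i].data());
  std::vector<double> xo(n), xr(n), xe(n), xc(n);
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> idx(n + 1);
    for (int i = 0; i <= n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<std::vector<double>> S2(n + 1);
    std::vector<double> f2(n + 1);
    for (int i = 0; i <= n; ++i) { S2[i] = S[idx[i]]; f2[i] = fv[idx[i]]; }
    S = S2; fv = f2;
    if (std::fabs(fv[n] - fv[0]) <=
        reltol * (std::fabs(fv[0]) + std::fabs(fv[n]) + 1e-10)) break;
    for (int j = 0; j < n; ++j) {
      xo[j] = 0.0;
      for (int i = 0; i < n; ++i) xo[j] += S[i][j];
      xo[j] /= n;
    }
    for (int j = 0; j < n; ++j) xr[j] = xo[j] + alpha * (xo[j] - S[n][j]);
    const double fr = f(xr.data());
    if (fr < fv[0]) {
      for (int j = 0; j < n; ++j) xe[j] = xo[j] + gamma * (xr[j] - xo[j]);
      const double fe = f(xe.data());
      if (fe < fr) { S[n] = xe; fv[n] = fe; }
      else { S[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      S[n] = xr; fv[n] = fr;
    } else {
      const bool outside = fr < fv[n];
      if (outside)
        for (int j = 0; j < n; ++j) xc[j] = xo[j] + rho * (xr[j] - xo[j]);
      else
        for (int j = 0; j < n; ++j) xc[j] = xo[j] - rho * (xo[j] - S[n][j]);
      const double fc = f(xc.data());
      if (fc < (outside ? fr : fv[n])) { S[n] = xc; fv[n] = fc; }
      else {
        for (int i = 1; i <= n; ++i) {
          for (int j = 0; j < n; ++j)
            S[i][j] = S[0][j] + sigma * (S[i][j] - S[0][j]);
          fv[i] = f(S[i].data());
        }
      }
    }
  }
  int besti = 0;
  for (int i = 1; i <= n; ++i) if (fv[i] < fv[besti]) besti = i;
  x = S[besti];
  return fv[besti];
}

} // namespace

// One restart of the pharmacodynamic fit: iterated Nelder-Mead rounds in
// the transformed space, stopping when the cost no longer improves.
// [[Rcpp::export(name = ".pd_fit_restart_cpp")]]
List pd_fit_restart_cpp(NumericVector z0, NumericVector c1, double h,
                        NumericVector t_obs, NumericVector f_obs,
                        NumericVector curve_D, NumericVector curve_f,
                        double k, NumericVector lo, NumericVector hi,
                        NumericVector prior_c, NumericVector prior_w,
                        double prior_lambda,
                        int maxit, double reltol, int rounds) {
  std::vector<double> lov(lo.begin(), lo.end()), hiv(hi.begin(), hi.end());
  std::vector<double> pc(prior_c.begin(), prior_c.end()),
      pw(prior_w.begin(), prior_w.end());
  PdObjective obj{c1, h, t_obs, f_obs, curve_D, curve_f, k, lov, hiv,
                  pc, pw, prior_lambda};
  std::vector<double> z(z0.begin(), z0.end());
  double v = R_PosInf;
  for (int r = 0; r < rounds; ++r) {
    std::vector<double> zr = z;
    const double vr = nelder_mead(obj, zr, maxit, reltol);
    if (vr >= v - 1e-11) { if (vr < v) { v = vr; z = zr; } break; }
    v = vr;
    z = zr;
  }
  double th[6];
  obj.theta_from_z(z.data(), th);
  return List::create(_["z"] = NumericVector(z.begin(), z.end()),
                      _["theta"] = NumericVector(th, th + 6),
                      _["value"] = v, _["evals"] = obj.evals);
}
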