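// Compiled hot path for the Bayesian observer: per-measurement posterior,
// center-of-mass pushforward moments, dense-grid endpoint optimization,
// exact per-node decision caches for the marginal likelihood, and the
// marginal response density given the decided endpoints.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

constexpr int MAXK = 8;

struct MixCom {
  int k;
  double w[MAXK], m[MAXK], v[MAXK];  // com-space weight, mean, variance
};

// Conjugate posterior over rho for one measurement, pushed through the
// center-of-mass map f_D(rho) = half * tanh(D rho / 2) by Gauss-Hermite
// moment matching (delta components map exactly).
MixCom com_posterior(double rho_m, const NumericVector& pw,
                     const NumericVector& pm, const NumericVector& psd,
                     double sigma_rho, double D, double half,
                     const NumericVector& ghx, const NumericVector& ghw) {
  const int k = pw.size();
  MixCom out;
  out.k = k;
  const double vr = sigma_rho * sigma_rho;
  double logw[MAXK], pmean[MAXK], pvar[MAXK];
  double maxlw = -INFINITY;
  for (int i = 0; i < k; ++i) {
    const double v0 = psd[i] * psd[i];
    const double pv = v0 + vr;
    const double d = rho_m - pm[i];
    logw[i] = std::log(pw[i]) - 0.5 * std::log(2.0 * M_PI * pv)
              - d * d / (2.0 * pv);
    pmean[i] = (vr * pm[i] + v0 * rho_m) / pv;
    pvar[i] = v0 * vr / pv;
    if (logw[i] > maxlw) maxlw = logw[i];
  }
  double tot = 0.0;
  for (int i = 0; i < k; ++i) {
    out.w[i] = std::exp(logw[i] - maxlw);
    tot += out.w[i];
  }
  const int n = ghx.size();
  const double sqrt_pi = std::sqrt(M_PI);
  for (int i = 0; i < k; ++i) {
    out.w[i] /= tot;
    if (pvar[i] <= 0.0) {
      out.m[i] = half * std::tanh(D * pmean[i] / 2.0);
      out.v[i] = 0.0;
    } else {
      const double s = std::sqrt(2.0 * pvar[i]);
      double m1 = 0.0, m2 = 0.0;
      for (int j = 0; j < n; ++j) {
        const double f = half * std::tanh(D * (pmean[i] + s * ghx[j]) / 2.0);
        const double wb = ghw[j] / sqrt_pi;
        m1 += wb * f;
        m2 += wb * f * f;
      }
      out.m[i] = m1;
      const double vv = m2 - m1 * m1;
      out.v[i] = vv > 0.0 ? vv : 0.0;
    }
  }
  return out;
}

// Adds amp * exp(-(x_j - m)^2 * inv2v) over the grid x_j = x0 + j h,
// j in [0, W), using the multiplicative Gaussian recurrence (two exps
// per row instead of one per point). Starts at the grid point nearest
// the peak to avoid dead underflow, and stops once contributions become
// negligible.
inline void add_gauss_row(double* dst, int W, double x0, double h,
                          double m, double amp, double inv2v) {
  if (amp == 0.0 || W <= 0) return;
  int jm = (int)std::floor((m - x0) / h + 0.5);
  if (jm < 0) jm = 0;
  if (jm > W - 1) jm = W - 1;
  const double w = std::exp(-2.0 * inv2v * h * h);
  const double d0 = x0 + jm * h - m;
  const double G0 = amp * std::exp(-d0 * d0 * inv2v);
  if (G0 < 1e-30) return;
  {  // rightward
    double G = G0;
    double u = std::exp(-inv2v * h * (2.0 * d0 + h));
    for (int j = jm; j < W; ++j) {
      dst[j] += G;
      G *= u;
      u *= w;
      if (G < 1e-30) break;
    }
  }
  {  // leftward
    double G = G0;
    double u = std::exp(-inv2v * (-h) * (2.0 * d0 - h));
    for (int j = jm - 1; j >= 0; --j) {
      G *= u;
      u *= w;
      dst[j] += G;
      if (G < 1e-30) break;
    }
  }
}

// Expected error gain on grid points lo + step * g, g in [0, ng).
void fill_egain(const MixCom& mx, double sigma_err, double lo, double step,
                int ng, std::vector<double>& E) {
  const double se2 = sigma_err * sigma_err;
  std::fill(E.begin(), E.begin() + ng, 0.0);
  for (int i = 0; i < mx.k; ++i) {
    const double vt = mx.v[i] + se2;
    const double amp = mx.w[i] * sigma_err / std::sqrt(vt);
    add_gauss_row(E.data(), ng, lo, step, mx.m[i], amp, 1.0 / (2.0 * vt));
  }
}

// Argmax over grid indices [i0, i1] with parabolic refinement.
// Near-ties break toward the smaller |s|.
double argmax_refine(const std::vector<double>& f, int i0, int i1,
                     double lo, double step, double slo, double shi) {
  int best = i0;
  double fb = f[i0];
  for (int i = i0 + 1; i <= i1; ++i) {
    const double tol = 1e-13 * std::max(1.0, std::fabs(fb));
    if (f[i] > fb + tol) {
      best = i;
      fb = f[i];
    } else if (f[i] > fb - tol &&
               std::fabs(lo + step * i) < std::fabs(lo + step * best)) {
      best = i;
      fb = f[i];
    }
  }
  double x = lo + step * best;
  if (best > i0 && best < i1) {
    const double den = f[best - 1] - 2.0 * f[best] + f[best + 1];
    if (den < 0.0) {
      double dx = 0.5 * step * (f[best - 1] - f[best + 1]) / den;
      if (dx > step) dx = step;
      if (dx < -step) dx = -step;
      x += dx;
    }
  }
  if (x < slo) x = slo;
  if (x > shi) x = shi;
  return x;
}

}  // namespace

// Exact two-stage decisions for vectors of (rho_m, b).
// [[Rcpp::export]]
List cpp_decide_trials(NumericVector rho_m, NumericVector b,
                       NumericVector pw, NumericVector pm, NumericVector psd,
                       double sigma_rho, double D, double alpha,
                       double inv_sigma_adj, double sigma_err, double half,
                       NumericVector ghx, NumericVector ghw, double s_step) {
  const int n = rho_m.size();
  const int ng = (int)std::floor(2.0 * half / s_step + 0.5) + 1;
  const double lo = -half;
  std::vector<double> E(ng), F(ng);
  NumericVector s_pre(n), s_star(n);
  const bool adj_active = (alpha > 0.0) && (inv_sigma_adj > 0.0);
  const double inv2a = 0.5 * inv_sigma_adj * inv_sigma_adj;
  for (int t = 0; t < n; ++t) {
    const MixCom mx = com_posterior(rho_m[t], pw, pm, psd, sigma_rho, D,
                                    half, ghx, ghw);
    fill_egain(mx, sigma_err, lo, s_step, ng, E);
    s_pre[t] = argmax_refine(E, 0, ng - 1, lo, s_step, -half, half);
    if (!adj_active) {
      s_star[t] = s_pre[t];
      continue;
    }
    const double r0 = s_pre[t] + b[t];
    std::copy(E.begin(), E.begin() + ng, F.begin());
    add_gauss_row(F.data(), ng, lo, s_step, r0, alpha, inv2a);
    s_star[t] = argmax_refine(F, 0, ng - 1, lo, s_step, -half, half);
  }
  return List::create(_["s_pre"] = s_pre, _["s_star"] = s_star);
}

// Per-node likelihood caches for maximum-likelihood fitting: every
// quadrature node of every trial gets its exact preliminary endpoint and
// its expected-error-gain curve over a window wide enough to contain the
// adjusted optimum for any perturbation in the data. Candidate
// adjustment-loss parameters then only pay for the adjustment term.
// [[Rcpp::export]]
List cpp_node_setup(NumericVector rho_m, NumericVector b,
                    NumericVector pw, NumericVector pm, NumericVector psd,
                    double sigma_rho, double D, double sigma_err,
                    double half, NumericVector ghx, NumericVector ghw,
                    double s_step, double margin) {
  const int N = rho_m.size();
  const int ng = (int)std::floor(2.0 * half / s_step + 0.5) + 1;
  const double lo = -half;
  double bmin = 0.0, bmax = 0.0;
  for (int i = 0; i < N; ++i) {
    bmin = std::min(bmin, b[i]);
    bmax = std::max(bmax, b[i]);
  }
  const int W = std::min(
      ng, (int)std::ceil((bmax - bmin + 2.0 * margin) / s_step) + 2);
  NumericVector s_pre(N);
  IntegerVector i0(N);
  NumericMatrix Ewin(W, N);  // one window per node, column-major
  std::vector<double> E(ng);
  for (int t = 0; t < N; ++t) {
    const MixCom mx = com_posterior(rho_m[t], pw, pm, psd, sigma_rho, D,
                                    half, ghx, ghw);
    fill_egain(mx, sigma_err, lo, s_step, ng, E);
    s_pre[t] = argmax_refine(E, 0, ng - 1, lo, s_step, -half, half);
    int start = (int)std::floor((s_pre[t] + bmin - margin - lo) / s_step);
    if (start < 0) start = 0;
    if (start > ng - W) start = ng - W;
    i0[t] = start;
    for (int j = 0; j < W; ++j) Ewin(j, t) = E[start + j];
  }
  return List::create(_["s_pre"] = s_pre, _["i0"] = i0, _["E"] = Ewin,
                      _["s_step"] = s_step, _["half"] = half);
}

// Adjusted endpoints for all nodes from the cached windows; the scan is
// restricted to each node's own [s_pre, s_pre + b] hull plus the margin.
// [[Rcpp::export]]
NumericVector cpp_star_from_setup(List setup, NumericVector b,
                                  double alpha, double inv_sigma_adj,
                                  double margin) {
  NumericVector s_pre = setup["s_pre"];
  IntegerVector i0 = setup["i0"];
  NumericMatrix Ewin = setup["E"];
  const double s_step = setup["s_step"];
  const double half = setup["half"];
  const int N = s_pre.size();
  const int W = Ewin.nrow();
  NumericVector out(N);
  if (alpha <= 0.0 || inv_sigma_adj <= 0.0) {
    for (int t = 0; t < N; ++t) out[t] = s_pre[t];
    return out;
  }
  const double inv2a = 0.5 * inv_sigma_adj * inv_sigma_adj;
  std::vector<double> F(W);
  for (int t = 0; t < N; ++t) {
    const double lo_t = -half + i0[t] * s_step;
    const double r0 = s_pre[t] + b[t];
    const double wlo = std::min((double)s_pre[t], r0) - margin;
    const double whi = std::max((double)s_pre[t], r0) + margin;
    int j0 = (int)std::floor((wlo - lo_t) / s_step);
    int j1 = (int)std::ceil((whi - lo_t) / s_step);
    if (j0 < 0) j0 = 0;
    if (j1 > W - 1) j1 = W - 1;
    for (int j = j0; j <= j1; ++j) F[j] = Ewin(j, t);
    add_gauss_row(F.data() + j0, j1 - j0 + 1, lo_t + j0 * s_step, s_step,
                  r0, alpha, inv2a);
    out[t] = argmax_refine(F, j0, j1, lo_t, s_step, -half, half);
  }
  return out;
}

// Per-trial log marginal density given the endpoint at every node.
// s_star is laid out node-major: K quadrature nodes per trial.
// [[Rcpp::export]]
NumericVector cpp_density_from_star(NumericVector r, NumericVector s_star,
                                    NumericVector ghw,
                                    double sigma_motor) {
  const int n = r.size();
  const int K = ghw.size();
  const double sqrt_pi = std::sqrt(M_PI);
  const double inv_norm = 1.0 / (sigma_motor * std::sqrt(2.0 * M_PI));
  const double inv2m = 1.0 / (2.0 * sigma_motor * sigma_motor);
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double dens = 0.0;
    for (int k = 0; k < K; ++k) {
      const double d = r[t] - s_star[t * K + k];
      dens += ghw[k] * inv_norm * std::exp(-d * d * inv2m);
    }
    dens /= sqrt_pi;
    out[t] = std::log(dens > 1e-300 ? dens : 1e-300);
  }
  return out;
}
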