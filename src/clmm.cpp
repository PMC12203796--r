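// Marginal log-likelihood of a cumulative link mixed model with a single
// per-animal random intercept, integrated by adaptive Gauss-Hermite
// quadrature around the per-animal conditional mode.
//
// Internal parameter vector (unconstrained):
//   par[0]            first threshold theta_1
//   par[1..K-2]       log successive threshold increments
//   par[K-1..K-2+p]   fixed-effect coefficients beta
//   par[last]         log sigma_u   (only when estimate_sigma != 0)
//
// Model: P(Y <= k | u_a) = F(theta_k - x'beta - u_a), u_a ~ N(0, sigma_u^2).

#include <Rcpp.h>
using namespace Rcpp;

static inline double link_cdf(double x, int link) {
  if (link == 0) {                  // logit
    if (x > 0) return 1.0 / (1.0 + std::exp(-x));
    double e = std::exp(x);
    return e / (1.0 + e);
  }
  return R::pnorm(x, 0.0, 1.0, 1, 0); // probit
}

static inline double link_pdf(double x, int link) {
  if (link == 0) {
    double f = link_cdf(x, 0);
    return f * (1.0 - f);
  }
  return R::dnorm(x, 0.0, 1.0, 0);
}

// derivative of the link density
static inline double link_dpdf(double x, int link) {
  if (link == 0) {
    double F = link_cdf(x, 0);
    double f = F * (1.0 - F);
    return f * (1.0 - 2.0 * F);
  }
  return -x * R::dnorm(x, 0.0, 1.0, 0);
}

struct ClmmData {
  const int *y;          // 1..K
  int n, K, p, nanim, link;
  const double *eta;     // X beta, length n
  const double *theta;   // K-1 increasing thresholds
  const std::vector<std::vector<int> > *rows; // rows per animal
};

// log f_a(u) = sum_i log P_i(u) + log phi(u; 0, sigma^2), with derivatives
static void animal_logf(const ClmmData &d, int a, double u, double sigma,
                        double &f, double &g, double &h) {
  f = 0.0; g = 0.0; h = 0.0;
  const std::vector<int> &rr = (*d.rows)[a];
  for (size_t j = 0; j < rr.size(); ++j) {
    int i = rr[j];
    int k = d.y[i];
    double aup = (k < d.K) ? d.theta[k - 1] - d.eta[i] - u : R_PosInf;
    double alo = (k > 1)   ? d.theta[k - 2] - d.eta[i] - u : R_NegInf;
    double Fa = (k < d.K) ? link_cdf(aup, d.link) : 1.0;
    double Fb = (k > 1)   ? link_cdf(alo, d.link) : 0.0;
    double P = Fa - Fb;
    if (P < 1e-300) P = 1e-300;
    double fa = (k < d.K) ? link_pdf(aup, d.link) : 0.0;
    double fb = (k > 1)   ? link_pdf(alo, d.link) : 0.0;
    double da = (k < d.K) ? link_dpdf(aup, d.link) : 0.0;
    double db = (k > 1)   ? link_dpdf(alo, d.link) : 0.0;
    f += std::log(P);
    double gp = (fb - fa) / P;          // d/du log P
    g += gp;
    h += (da - db) / P - gp * gp;       // d2/du2 log P
  }
  f += -0.5 * u * u / (sigma * sigma) - std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  g += -u / (sigma * sigma);
  h += -1.0 / (sigma * sigma);
}

// value-only version for quadrature points (no derivatives)
static double animal_logf_only(const ClmmData &d, int a, double u, double sigma) {
  double f = 0.0;
  const std::vector<int> &rr = (*d.rows)[a];
  for (size_t j = 0; j < rr.size(); ++j) {
    int i = rr[j];
    int k = d.y[i];
    double Fa = (k < d.K) ? link_cdf(d.theta[k - 1] - d.eta[i] - u, d.link) : 1.0;
    double Fb = (k > 1)   ? link_cdf(d.theta[k - 2] - d.eta[i] - u, d.link) : 0.0;
    double P = Fa - Fb;
    if (P < 1e-300) P = 1e-300;
    f += std::log(P);
  }
  f += -0.5 * u * u / (sigma * sigma) - std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  return f;
}

// negative marginal log-likelihood
static double clmm_nll_core(const std::vector<double> &par,
                            const IntegerVector &y, const NumericMatrix &X,
                            const std::vector<std::vector<int> > &rows,
                            int K, const NumericVector &ghx, const NumericVector &ghw,
                            int link, double sigma_fixed, int estimate_sigma) {
  int n = y.size();
  int p = X.ncol();
  // thresholds
  std::vector<double> theta(K - 1);
  theta[0] = par[0];
  for (int k = 1; k < K - 1; ++k) theta[k] = theta[k - 1] + std::exp(par[k]);
  // eta = X beta
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    double b = par[K - 1 + j];
    if (b != 0.0) {
      const double *xc = &X(0, j);
      for (int i = 0; i < n; ++i) eta[i] += xc[i] * b;
    }
  }
  double sigma;
  if (estimate_sigma) {
    double ls = par[K - 1 + p];
    if (ls > 20.0) ls = 20.0;
    if (ls < -20.0) ls = -20.0;
    sigma = std::exp(ls);
  } else {
    sigma = sigma_fixed;
  }

  ClmmData d;
  d.y = INTEGER(y); d.n = n; d.K = K; d.p = p; d.link = link;
  d.nanim = (int) rows.size();
  d.eta = eta.data(); d.theta = theta.data(); d.rows = &rows;

  double ll = 0.0;
  if (sigma <= 1e-10) {
    // degenerate: fixed-effects model, u = 0 with no prior contribution
    for (int i = 0; i < n; ++i) {
      int k = y[i];
      double Fa = (k < K) ? link_cdf(theta[k - 1] - eta[i], link) : 1.0;
      double Fb = (k > 1) ? link_cdf(theta[k - 2] - eta[i], link) : 0.0;
      double P = Fa - Fb;
      if (P < 1e-300) P = 1e-300;
      ll += std::log(P);
    }
    return -ll;
  }

  int nq = ghx.size();
  for (int a = 0; a < d.nanim; ++a) {
    // Newton search for the conditional mode (log f is concave for
    // logit/probit links, so undamped Newton with step halving suffices)
    double u = 0.0, f, g, h;
    animal_logf(d, a, u, sigma, f, g, h);
    for (int it = 0; it < 50; ++it) {
      double hh = (h < -1e-12) ? h : -1e-12;
      double step = -g / hh;
      if (step > 10.0 * sigma) step = 10.0 * sigma;
      if (step < -10.0 * sigma) step = -10.0 * sigma;
      double unew = u + step, fn, gn, hn;
      animal_logf(d, a, unew, sigma, fn, gn, hn);
      int halv = 0;
      while (fn < f && halv < 30) {
        step *= 0.5; unew = u + step;
        animal_logf(d, a, unew, sigma, fn, gn, hn);
        ++halv;
      }
      double moved = std::fabs(unew - u);
      u = unew; f = fn; g = gn; h = hn;
      if (std::fabs(g) < 1e-8 || moved < 1e-10) break;
    }
    double hcur = (h < -1e-12) ? -h : 1e-12;  // curvature at mode
    if (nq == 1) {
      ll += f + 0.5 * std::log(2.0 * M_PI / hcur); // Laplace
    } else {
      double s = std::sqrt(2.0 / hcur);
      double acc = 0.0;
      for (int q = 0; q < nq; ++q) {
        double fq = animal_logf_only(d, a, u + s * ghx[q], sigma);
        acc += ghw[q] * std::exp(ghx[q] * ghx[q] + fq - f);
      }
      ll += f + std::log(s * acc);
    }
  }
  return -ll;
}

static std::vector<std::vector<int> > build_rows(const IntegerVector &animal, int nanim) {
  std::vector<std::vector<int> > rows(nanim);
  for (int i = 0; i < animal.size(); ++i) rows[animal[i]].push_back(i);
  return rows;
}

// [[Rcpp::export]]
double clmm_nll_cpp(NumericVector par, IntegerVector y, NumericMatrix X,
                    IntegerVector animal, int nanim, int K,
                    NumericVector ghx, NumericVector ghw, int link,
                    double sigma_fixed, int estimate_sigma) {
  std::vector<double> p(par.begin(), par.end());
  std::vector<std::vector<int> > rows = build_rows(animal, nanim);
  return clmm_nll_core(p, y, X, rows, K, ghx, ghw, link, sigma_fixed, estimate_sigma);
}

// central-difference gradient of the negative log-likelihood
// [[Rcpp::export]]
NumericVector clmm_nll_grad_cpp(NumericVector par, IntegerVector y, NumericMatrix X,
                                IntegerVector animal, int nanim, int K,
                                NumericVector ghx, NumericVector ghw, int link,
                                double sigma_fixed, int estimate_sigma) {
  int np = par.size();
  std::vector<double> p(par.begin(), par.end());
  std::vector<std::vector<int> > rows = build_rows(animal, nanim);
  NumericVector grad(np);
  double f0 = clmm_nll_core(p, y, X, rows, K, ghx, ghw, link, sigma_fixed, estimate_sigma);
  for (int j = 0; j < np; ++j) {
    double h = 1e-6 * (1.0 + std::fabs(p[j]));
    double keep = p[j];
    p[j] = keep + h;
    double f1 = clmm_nll_core(p, y, X, rows, K, ghx, ghw, link, sigma_fixed, estimate_sigma);
    p[j] = keep;
    grad[j] = (f1 - f0) / h;
  }
  return grad;
}

// Trailing-window rolling quantile (type-7), window includes the current
// sample; windows at the start shrink to the available samples.
// [[Rcpp::export]]
NumericVector roll_quantile_cpp(NumericVector x, int window, double prob) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    int lo = i - window + 1;
    if (lo < 0) lo = 0;
    int m = i - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + i + 1);
    double h = prob * (m - 1);
    int k = (int) std::floor(h);
    double frac = h - k;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double vk = buf[k];
    double v = vk;
    if (frac > 0 && k + 1 < m) {
      double vk1 = *std::min_element(buf.begin() + k + 1, buf.end());
      v = vk + frac * (vk1 - vk);
    }
    out[i] = v;
  }
  return out;
}
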