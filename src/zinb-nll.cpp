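#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood of the zero-inflated negative binomial
// random-intercept model, integrated over the subject intercept by adaptive
// Gauss-Hermite quadrature. Cells of one subject share a single mean
// mu_i = exp(gamma0 + b_i + slope * x_i) (no cell-level covariates), so the
// per-subject conditional log-likelihood collapses to sufficient statistics
// of the counts and each quadrature evaluation is O(1).
//
// Parameters (all unconstrained): gamma0, slope, log sd_int, logit zero_p,
// log theta.

struct SubjLik {
  double n0;     // zero cells
  double npos;   // positive cells
  double sy;     // sum of positive counts
  double clg;    // sum lgamma(y+theta) - npos*lgamma(theta) - sum lgamma(y+1)
  double eta0;   // gamma0 + slope * x_i
  double zp, th, log_th;

  // conditional log-likelihood of subject's cells at intercept offset b
  double ll(double b) const {
    double eta = eta0 + b;
    double lthmu = (eta > log_th) ? eta + std::log1p(std::exp(log_th - eta))
                                  : log_th + std::log1p(std::exp(eta - log_th));
    double logp0 = th * (log_th - lthmu);
    double out = 0.0;
    if (n0 > 0.0) {
      // log(zp + (1-zp) * exp(logp0)), stable for either term dominating
      double a = std::log1p(-zp) + logp0;
      double lz = (zp > 0.0) ? std::log(zp) : -INFINITY;
      double mx = std::max(a, lz);
      out += n0 * (mx + std::log(std::exp(a - mx) + std::exp(lz - mx)));
    }
    if (npos > 0.0) {
      out += npos * std::log1p(-zp) + clg +
             npos * th * (log_th - lthmu) + sy * (eta - lthmu);
    }
    return out;
  }

  // first/second derivatives of ll with respect to b
  void dll(double b, double &d1, double &d2) const {
    double mu = std::exp(eta0 + b);
    double frac = mu / (th + mu);
    d1 = 0.0; d2 = 0.0;
    if (npos > 0.0) {
      d1 += sy - (sy + npos * th) * frac;
      d2 += -(sy + npos * th) * th * mu / ((th + mu) * (th + mu));
    }
    if (n0 > 0.0) {
      double p0 = std::exp(th * (log_th - std::log(th + mu)));
      double A = (1.0 - zp) * p0;
      double s = zp + A;
      if (s < 1e-300) s = 1e-300;
      double r = -th * frac;                              // d log p0 / d eta
      double rp = -th * th * mu / ((th + mu) * (th + mu)); // d r / d eta
      double g = A * r / s;
      d1 += n0 * g;
      d2 += n0 * (A * (r * r + rp) / s - g * g);
    }
  }
};

// [[Rcpp::export(name = ".zinb_marginal_nll")]]
double zinb_marginal_nll(NumericVector par, IntegerVector ypos,
                         IntegerVector subj, NumericVector n0,
                         NumericVector x, NumericVector ghz,
                         NumericVector ghw) {
  const double g0 = par[0], beta = par[1];
  const double sb = std::exp(par[2]);
  const double zp = 1.0 / (1.0 + std::exp(-par[3]));
  const double th = std::exp(par[4]);
  const double log_th = par[4];
  const int n = x.size(), K = ghz.size();

  std::vector<double> sy(n, 0.0), npos(n, 0.0), clg(n, 0.0);
  const double lg_th = lgamma(th);
  for (int c = 0; c < ypos.size(); ++c) {
    int i = subj[c];
    double y = (double) ypos[c];
    sy[i] += y;
    npos[i] += 1.0;
    clg[i] += lgamma(y + th) - lgamma(y + 1.0);
  }

  const double sb2 = sb * sb;
  const double point_mass = (sb < 1e-6);
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    SubjLik s;
    s.n0 = n0[i]; s.npos = npos[i]; s.sy = sy[i];
    s.clg = clg[i] - npos[i] * lg_th;
    s.eta0 = g0 + beta * x[i];
    s.zp = zp; s.th = th; s.log_th = log_th;

    if (point_mass) { // degenerate random effect: density at b = 0
      nll -= s.ll(0.0);
      continue;
    }

    // Newton search for the mode of h(b) = ll(b) - b^2 / (2 sb^2)
    double b = 0.0, d1, d2, h2 = -1.0 / sb2;
    for (int it = 0; it < 100; ++it) {
      s.dll(b, d1, d2);
      double hd1 = d1 - b / sb2;
      h2 = d2 - 1.0 / sb2;
      if (h2 > -1e-8) h2 = -1.0; // safeguard rare non-concave pockets
      double step = hd1 / h2;
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      b -= step;
      if (std::fabs(hd1) < 1e-9 || std::fabs(step) < 1e-12) break;
    }
    s.dll(b, d1, d2);
    h2 = d2 - 1.0 / sb2;
    if (h2 > -1e-8) h2 = -1.0 / sb2;
    double sig = 1.0 / std::sqrt(-h2);

    // adaptive GH: log integral of exp(h(b)) db
    double lognorm = -0.918938533204672742 - std::log(sb); // -log(sb*sqrt(2pi))
    double mx = -INFINITY;
    std::vector<double> lt(K);
    for (int k = 0; k < K; ++k) {
      double bk = b + M_SQRT2 * sig * ghz[k];
      lt[k] = std::log(ghw[k]) + ghz[k] * ghz[k] + s.ll(bk) -
              0.5 * bk * bk / sb2 + lognorm;
      if (lt[k] > mx) mx = lt[k];
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(lt[k] - mx);
    nll -= mx + std::log(acc) + 0.5 * std::log(2.0) + std::log(sig);
  }
  return nll;
}
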