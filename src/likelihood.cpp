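#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Half-normal point-transect cell probabilities for one value of sigma.
// Individuals uniform in the disc of radius B => radial density 2r/B^2, so
//   pi_b = int_{r_b}^{r_{b+1}} exp(-r^2/(2 s^2)) 2r/B^2 dr
//        = (2 s^2 / B^2) * (exp(-r_b^2/(2 s^2)) - exp(-r_{b+1}^2/(2 s^2))).
// Returns the sum over bins (total detection probability given availability).
static inline double cell_probs(const double* brk, const int nb, const double B2,
                                const double sigma, double* pi) {
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double c = 2.0 * sigma * sigma / B2;
  double prev = std::exp(-brk[0] * brk[0] * inv2s2);
  double tot = 0.0;
  for (int b = 0; b < nb; ++b) {
    const double nxt = std::exp(-brk[b + 1] * brk[b + 1] * inv2s2);
    pi[b] = c * (prev - nxt);
    tot += pi[b];
    prev = nxt;
  }
  return tot;
}

static inline double inv_logit(const double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  const double e = std::exp(x);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
NumericVector C_cell_probs(NumericVector breaks, double sigma) {
  const int nb = breaks.size() - 1;
  const double B = breaks[nb];
  NumericVector out(nb + 1);
  double tot = cell_probs(breaks.begin(), nb, B * B, sigma, out.begin());
  out[nb] = 1.0 - tot; // undetected cell
  return out;
}

// Marginal log-likelihood of a structured (replicated) dataset.
//
// Hierarchy: M_i ~ Poisson(lambda_i); N_{i,j} ~ Binomial(M_i, phi_{i,j});
// y_{i,j} ~ Multinomial(N_{i,j}, pi_{i,j}).  N and y collapse to
// y_{i,j} | M_i ~ Multinomial(M_i, (phi*pi_1, ..., phi*pi_nb, 1 - phi*sum(pi)))
// and M is summed to a site-specific truncation K_i.  Log-normal residuals on
// lambda (site level, sd_a) and sigma (site-visit level, sd_d) are integrated
// by Gauss-Hermite quadrature; ghx/ghw are standard-normal nodes and
// normalized weights.  rho (length I) enables zero-inflation; length 0
// disables it.  K_fixed > 0 forces a common truncation, otherwise K_i is the
// upper 1e-10 Poisson tail quantile at the largest abundance node.
// [[Rcpp::export]]
double C_structured_ll(IntegerMatrix y, int I, int J,
                       NumericVector breaks,
                       NumericVector log_lambda,
                       NumericVector logit_phi,
                       NumericVector log_sigma,
                       double sd_a, double sd_d,
                       NumericVector ghx, NumericVector ghw,
                       NumericVector rho,
                       int K_fixed) {
  const int nb = breaks.size() - 1;
  const double B = breaks[nb];
  const double B2 = B * B;
  const int n_a = (sd_a > 0.0) ? ghx.size() : 1;
  const int n_d = (sd_d > 0.0) ? ghx.size() : 1;
  const bool zip = rho.size() > 0;

  // per-row total counts and multinomial denominator constants
  std::vector<int> ytot(I * J);
  std::vector<double> cy(I * J);
  int maxy_all = 0;
  for (int r = 0; r < I * J; ++r) {
    int t = 0; double c = 0.0;
    for (int b = 0; b < nb; ++b) {
      t += y(r, b);
      c += std::lgamma((double)y(r, b) + 1.0);
    }
    ytot[r] = t; cy[r] = c;
    if (t > maxy_all) maxy_all = t;
  }

  // site truncation bounds
  // Conditional on the observed totals the M-sum behaves like a Poisson
  // tail shifted by the largest per-visit count, so the truncation must
  // cover ymax plus the upper tail of the (thinned) Poisson rate.
  std::vector<int> K_site(I);
  int K_max = 0;
  const double xa_max = (n_a > 1) ? ghx[ghx.size() - 1] : 0.0;
  for (int i = 0; i < I; ++i) {
    int ymax = 0;
    for (int j = 0; j < J; ++j) if (ytot[i * J + j] > ymax) ymax = ytot[i * J + j];
    int K;
    if (K_fixed > 0) {
      K = (K_fixed >= ymax) ? K_fixed : ymax;
    } else {
      const double lam_hi = std::exp(log_lambda[i] + sd_a * std::fabs(xa_max));
      if (!(lam_hi < 4000.0)) return R_NegInf; // degenerate region guard
      K = ymax + (int)R::qpois(1e-12, lam_hi, 0, 0) + 2;
    }
    if (K > 20000) return R_NegInf;
    K_site[i] = K;
    if (K > K_max) K_max = K;
  }

  // lgamma lookup: lgam[k] = lgamma(k)
  std::vector<double> lgam(K_max + 2);
  lgam[0] = 0.0;
  for (int k = 1; k <= K_max + 1; ++k) lgam[k] = std::lgamma((double)k);

  std::vector<double> pi(nb), P(K_max + 1), prod(K_max + 1);
  double ll = 0.0;

  for (int i = 0; i < I; ++i) {
    const int K = K_site[i];
    double scale_log = 0.0;
    bool allzero = true;
    for (int M = 0; M <= K; ++M) prod[M] = 1.0;

    for (int j = 0; j < J; ++j) {
      const int r = i * J + j;
      const int yt = ytot[r];
      if (yt > 0) allzero = false;
      const double phi = inv_logit(logit_phi[r]);
      for (int M = 0; M <= K; ++M) P[M] = 0.0;

      for (int t = 0; t < n_d; ++t) {
        const double xd = (n_d > 1) ? ghx[t] : 0.0;
        const double wd = (n_d > 1) ? ghw[t] : 1.0;
        const double sigma = std::exp(log_sigma[r] + sd_d * xd);
        const double sumpi = cell_probs(breaks.begin(), nb, B2, sigma, pi.data());
        // log multinomial kernel at M = yt (no survivor term yet)
        double logq = 0.0;
        bool ok = true;
        for (int b = 0; b < nb; ++b) {
          if (y(i * J + j, b) > 0) {
            const double p = phi * pi[b];
            if (p <= 0.0) { ok = false; break; }
            logq += y(r, b) * std::log(p);
          }
        }
        if (!ok) continue; // zero-probability cell with a count: node contributes 0
        const double S = 1.0 - phi * sumpi; // "undetected" cell probability
        double term = std::exp(lgam[yt + 1] - cy[r] + logq);
        P[yt] += wd * term;
        for (int M = yt + 1; M <= K; ++M) {
          term *= S * (double)M / (double)(M - yt);
          P[M] += wd * term;
        }
      }
      double mx = 0.0;
      for (int M = 0; M <= K; ++M) {
        prod[M] *= P[M];
        if (prod[M] > mx) mx = prod[M];
      }
      if (mx > 0.0 && mx < 1e-220) {
        const double inv = 1.0 / mx;
        for (int M = 0; M <= K; ++M) prod[M] *= inv;
        scale_log += std::log(mx);
      }
    }

    double lik = 0.0;
    for (int u = 0; u < n_a; ++u) {
      const double xu = (n_a > 1) ? ghx[u] : 0.0;
      const double wu = (n_a > 1) ? ghw[u] : 1.0;
      const double lam = std::exp(log_lambda[i] + sd_a * xu);
      double pw = std::exp(-lam), s = 0.0;
      for (int M = 0; M <= K; ++M) {
        s += pw * prod[M];
        pw *= lam / (double)(M + 1);
      }
      lik += wu * s;
    }

    double ll_i = std::log(lik) + scale_log;
    if (zip) {
      const double rh = rho[i];
      if (allzero) {
        ll_i = std::log(rh + (1.0 - rh) * std::exp(ll_i));
      } else {
        ll_i = std::log1p(-rh) + ll_i;
      }
    }
    ll += ll_i;
  }
  return ll;
}

// Marginal log-likelihood of single-visit semi-structured lists.  With one
// visit the Poisson-Binomial-Multinomial chain collapses exactly: bin counts
// are independent Poisson(lambda_i * phi_i * pi_b).  Residuals integrated by
// Gauss-Hermite as above.
// [[Rcpp::export]]
double C_lists_ll(IntegerMatrix y,
                  NumericVector breaks,
                  NumericVector log_lambda,
                  NumericVector logit_phi,
                  NumericVector log_sigma,
                  double sd_a, double sd_d,
                  NumericVector ghx, NumericVector ghw,
                  NumericVector rho) {
  const int n = y.nrow();
  const int nb = breaks.size() - 1;
  const double B = breaks[nb];
  const double B2 = B * B;
  const int n_a = (sd_a > 0.0) ? ghx.size() : 1;
  const int n_d = (sd_d > 0.0) ? ghx.size() : 1;
  const bool zip = rho.size() > 0;

  std::vector<double> pi(nb), sumpi(n_d), ylogpi(n_d);
  std::vector<bool> ok(n_d);
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    int yt = 0; double cy = 0.0;
    for (int b = 0; b < nb; ++b) {
      yt += y(i, b);
      cy += std::lgamma((double)y(i, b) + 1.0);
    }
    const double phi = inv_logit(logit_phi[i]);
    const double logphi = std::log(phi);

    for (int t = 0; t < n_d; ++t) {
      const double xd = (n_d > 1) ? ghx[t] : 0.0;
      const double sigma = std::exp(log_sigma[i] + sd_d * xd);
      sumpi[t] = cell_probs(breaks.begin(), nb, B2, sigma, pi.data());
      double s = 0.0; bool good = true;
      for (int b = 0; b < nb; ++b) {
        if (y(i, b) > 0) {
          if (pi[b] <= 0.0) { good = false; break; }
          s += y(i, b) * std::log(pi[b]);
        }
      }
      ok[t] = good; ylogpi[t] = s;
    }

    double lik = 0.0;
    for (int u = 0; u < n_a; ++u) {
      const double xu = (n_a > 1) ? ghx[u] : 0.0;
      const double wu = (n_a > 1) ? ghw[u] : 1.0;
      const double loglam = log_lambda[i] + sd_a * xu;
      const double lam = std::exp(loglam);
      for (int t = 0; t < n_d; ++t) {
        if (!ok[t]) continue;
        const double wd = (n_d > 1) ? ghw[t] : 1.0;
        // yt == 0 must not touch logphi (0 * -Inf when phi underflows)
        const double lp = (yt > 0 ? yt * (loglam + logphi) + ylogpi[t] - cy
                                  : 0.0)
          - lam * phi * sumpi[t];
        lik += wu * wd * std::exp(lp);
      }
    }

    double ll_i = std::log(lik);
    if (zip) {
      const double rh = rho[i];
      if (yt == 0) ll_i = std::log(rh + (1.0 - rh) * std::exp(ll_i));
      else ll_i = std::log1p(-rh) + ll_i;
    }
    ll += ll_i;
  }
  return ll;
}
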