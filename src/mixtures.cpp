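// EM inner loops for the two mixture models used by the pipeline:
//  - a constrained 3-component Gaussian mixture (empirical-null estimation of
//    bias and inflation of EWAS test statistics), and
//  - a 3-component beta mixture (unmethylated / hemimethylated / methylated
//    states for quantile calibration of methylation profiles).
// Both are plain EM with fixed iteration caps; restarts are orchestrated in R.

#include <Rcpp.h>
using namespace Rcpp;

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.918938533204672742 - std::log(sd) - 0.5 * z * z;
}

// Constrained Gaussian mixture: component 0 is the central null with mean mu0
// and sd sigma0; component 1 has mean <= mu0, component 2 has mean >= mu0,
// both with sd >= sigma0. Returns parameters at convergence plus loglik.
// [[Rcpp::export(name = ".em_gaussian3")]]
List em_gaussian3(NumericVector z,
                  NumericVector mu_init, NumericVector sd_init,
                  NumericVector w_init,
                  int max_iter = 500, double tol = 1e-8) {
  const int n = z.size();
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sd(sd_init.begin(), sd_init.end());
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> r0(n), r1(n), r2(n);
  double loglik = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // E-step (per-component constants hoisted out of the data loop)
    double c0 = std::log(w[0]) - std::log(sd[0]) - 0.918938533204672742;
    double c1 = std::log(w[1]) - std::log(sd[1]) - 0.918938533204672742;
    double c2 = std::log(w[2]) - std::log(sd[2]) - 0.918938533204672742;
    double h0 = 0.5 / (sd[0] * sd[0]), h1 = 0.5 / (sd[1] * sd[1]),
           h2 = 0.5 / (sd[2] * sd[2]);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double d0i = z[i] - mu[0], d1i = z[i] - mu[1], d2i = z[i] - mu[2];
      double l0 = c0 - h0 * d0i * d0i;
      double l1 = c1 - h1 * d1i * d1i;
      double l2 = c2 - h2 * d2i * d2i;
      double m = std::max(l0, std::max(l1, l2));
      double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m), e2 = std::exp(l2 - m);
      double s = e0 + e1 + e2;
      r0[i] = e0 / s; r1[i] = e1 / s; r2[i] = e2 / s;
      ll += m + std::log(s);
    }
    if (R_finite(loglik) && std::fabs(ll - loglik) < tol * (std::fabs(loglik) + 1.0)) {
      loglik = ll;
      converged = true;
      break;
    }
    loglik = ll;

    // M-step
    double n0 = 0, n1 = 0, n2 = 0;
    double s0 = 0, s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      n0 += r0[i]; n1 += r1[i]; n2 += r2[i];
      s0 += r0[i] * z[i]; s1 += r1[i] * z[i]; s2 += r2[i] * z[i];
    }
    // empty components keep their previous location but lose their weight
    if (n0 > 1e-6) mu[0] = s0 / n0;
    if (n1 > 1e-6) mu[1] = s1 / n1;
    if (n2 > 1e-6) mu[2] = s2 / n2;
    double v0 = 0, v1 = 0, v2 = 0;
    for (int i = 0; i < n; ++i) {
      double d0 = z[i] - mu[0], d1 = z[i] - mu[1], d2 = z[i] - mu[2];
      v0 += r0[i] * d0 * d0; v1 += r1[i] * d1 * d1; v2 += r2[i] * d2 * d2;
    }
    if (n0 > 1e-6) sd[0] = std::sqrt(std::max(v0 / n0, 1e-12));
    if (n1 > 1e-6) sd[1] = std::sqrt(std::max(v1 / n1, 1e-12));
    if (n2 > 1e-6) sd[2] = std::sqrt(std::max(v2 / n2, 1e-12));
    w[0] = std::max(n0 / n, 1e-6); w[1] = std::max(n1 / n, 1e-6);
    w[2] = std::max(n2 / n, 1e-6);
    double tot = w[0] + w[1] + w[2];
    w[0] /= tot; w[1] /= tot; w[2] /= tot;

    // constraint projection: alt means bracket the null and stay separated
    // from it by at least one null sd (otherwise an alternative component can
    // mimic the null and split its weight); alt sds >= null sd
    if (mu[1] > mu[0] - sd[0]) mu[1] = mu[0] - sd[0];
    if (mu[2] < mu[0] + sd[0]) mu[2] = mu[0] + sd[0];
    if (sd[1] < sd[0]) sd[1] = sd[0];
    if (sd[2] < sd[0]) sd[2] = sd[0];
  }

  return List::create(
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sd"] = NumericVector(sd.begin(), sd.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["loglik"] = loglik,
    _["converged"] = converged,
    _["iterations"] = iter);
}

// Beta mixture EM with moment-matching M-step (weighted mean/variance mapped
// to shape parameters). The moment-matching update is not guaranteed to
// increase the likelihood monotonically, so the best-likelihood iterate is
// tracked and returned. Component order is not enforced here; R sorts by mean.
// [[Rcpp::export(name = ".em_beta3")]]
List em_beta3(NumericVector x,
              NumericVector a_init, NumericVector b_init, NumericVector w_init,
              int max_iter = 200, double tol = 1e-6) {
  const int n = x.size();
  const int k = a_init.size();
  std::vector<double> a(a_init.begin(), a_init.end());
  std::vector<double> b(b_init.begin(), b_init.end());
  std::vector<double> w(w_init.begin(), w_init.end());
  NumericMatrix resp(n, k);
  double loglik = R_NegInf;
  double best_ll = R_NegInf;
  std::vector<double> best_a(a), best_b(b), best_w(w);
  bool converged = false;
  int iter = 0;

  std::vector<double> lx(n), l1x(n);
  for (int i = 0; i < n; ++i) {
    lx[i] = std::log(x[i]);
    l1x[i] = std::log1p(-x[i]);
  }

  for (iter = 0; iter < max_iter; ++iter) {
    double ll = 0.0;
    std::vector<double> lw(k), lb(k);
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]);
      lb[j] = R::lbeta(a[j], b[j]);
    }
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      std::vector<double> lc(k);
      for (int j = 0; j < k; ++j) {
        lc[j] = lw[j] + (a[j] - 1.0) * lx[i] + (b[j] - 1.0) * l1x[i] - lb[j];
        if (lc[j] > m) m = lc[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(lc[j] - m);
      for (int j = 0; j < k; ++j) resp(i, j) = std::exp(lc[j] - m) / s;
      ll += m + std::log(s);
    }
    if (ll > best_ll) {
      best_ll = ll;
      best_a.assign(a.begin(), a.end());
      best_b.assign(b.begin(), b.end());
      best_w.assign(w.begin(), w.end());
    }
    if (R_finite(loglik) && std::fabs(ll - loglik) < tol * (std::fabs(loglik) + 1.0)) {
      loglik = ll;
      converged = true;
      break;
    }
    loglik = ll;

    for (int j = 0; j < k; ++j) {
      double nj = 0, mj = 0;
      for (int i = 0; i < n; ++i) { nj += resp(i, j); mj += resp(i, j) * x[i]; }
      if (nj < 1e-8) { nj = 1e-8; }
      mj /= nj;
      double vj = 0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mj;
        vj += resp(i, j) * d * d;
      }
      vj /= nj;
      // moment matching, guarded against degenerate variance
      vj = std::max(vj, 1e-6);
      double cap = mj * (1.0 - mj);
      if (vj >= cap) vj = 0.99 * cap;
      double common = cap / vj - 1.0;
      a[j] = std::max(mj * common, 1e-2);
      b[j] = std::max((1.0 - mj) * common, 1e-2);
      w[j] = nj / n;
    }
    double wsum = w[0];
    for (int j = 1; j < k; ++j) wsum += w[j];
    for (int j = 0; j < k; ++j) w[j] /= wsum;
  }

  return List::create(
    _["a"] = NumericVector(best_a.begin(), best_a.end()),
    _["b"] = NumericVector(best_b.begin(), best_b.end()),
    _["w"] = NumericVector(best_w.begin(), best_w.end()),
    _["loglik"] = best_ll,
    _["converged"] = converged,
    _["iterations"] = iter);
}
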