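// EM inner loop for the von Mises + uniform mixture. One call runs every
// restart on a precomputed cos(error) vector and returns the best by
// log-likelihood. Bessel functions come from Rmath in exponentially scaled
// form, so kappa up to the overflow guard is safe.

#include <Rcpp.h>
using namespace Rcpp;

static const double KAPPA_MAX_C = 700.0;

static double a1_ratio(double k) {
  if (k <= 0.0) return 0.0;
  return R::bessel_i(k, 1.0, 2.0) / R::bessel_i(k, 0.0, 2.0);
}

// Newton inversion of the mean resultant length (three-branch start)
static double a1inv_c(double ri) {
  if (ri <= 0.0) return 0.0;
  if (ri >= 1.0) return KAPPA_MAX_C;
  double k;
  if (ri < 0.53) {
    k = 2.0 * ri + ri * ri * ri + 5.0 * std::pow(ri, 5) / 6.0;
  } else if (ri < 0.85) {
    k = -0.4 + 1.39 * ri + 0.43 / (1.0 - ri);
  } else {
    k = 1.0 / (ri * ri * ri - 4.0 * ri * ri + 3.0 * ri);
  }
  if (k < 1e-8) k = 1e-8;
  if (k > KAPPA_MAX_C) k = KAPPA_MAX_C;
  for (int i = 0; i < 25; ++i) {
    double r = a1_ratio(k);
    double f = r - ri;
    if (std::fabs(f) < 1e-12) break;
    double knew = k - f / (1.0 - r / k - r * r);
    if (knew < k / 10.0) knew = k / 10.0;
    if (knew > KAPPA_MAX_C) knew = KAPPA_MAX_C;
    if (std::fabs(knew - k) < 1e-10) { k = knew; break; }
    k = knew;
  }
  return k;
}

// [[Rcpp::export(name = ".a1inv_cpp")]]
NumericVector a1inv_vec_cpp(NumericVector r) {
  const int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = a1inv_c(r[i]);
  return out;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector cos_e, NumericVector pm0, NumericVector kappa0,
                double tol, int max_iter, bool keep_trace) {
  const int n = cos_e.size();
  const double u = 1.0 / (2.0 * M_PI);
  double best_ll = R_NegInf, best_pm = NA_REAL, best_kappa = NA_REAL;
  bool best_conv = false;
  int best_iter = 0;
  std::vector<double> best_trace;
  const int n_starts = pm0.size() * kappa0.size();
  NumericVector lls(n_starts);
  int start_idx = 0;

  for (int a = 0; a < pm0.size(); ++a) {
    for (int b = 0; b < kappa0.size(); ++b) {
      double pm = pm0[a];
      if (pm < 1e-6) pm = 1e-6;
      if (pm > 1.0 - 1e-6) pm = 1.0 - 1e-6;
      double kappa = kappa0[b];
      double ll = R_NegInf, ll_old = R_NegInf;
      bool converged = false;
      int iter = 0;
      std::vector<double> trace;
      for (iter = 1; iter <= max_iter; ++iter) {
        // E step: responsibilities and log-likelihood
        double norm = 2.0 * M_PI * R::bessel_i(kappa, 0.0, 2.0);
        double sw = 0.0, swc = 0.0;
        ll = 0.0;
        for (int i = 0; i < n; ++i) {
          double f = std::exp(kappa * (cos_e[i] - 1.0)) / norm;
          double num = pm * f;
          double den = num + (1.0 - pm) * u;
          double w = num / den;
          sw += w;
          swc += w * cos_e[i];
          ll += std::log(den);
        }
        if (keep_trace) trace.push_back(ll);
        if (R_FINITE(ll_old) && std::fabs(ll - ll_old) < tol) {
          converged = true;
          break;
        }
        if (iter == max_iter) break;
        ll_old = ll;
        // M step
        pm = sw / n;
        if (pm < 1e-6) pm = 1e-6;
        if (pm > 1.0 - 1e-6) pm = 1.0 - 1e-6;
        double cbar = (sw > 0.0) ? swc / sw : 0.0;
        kappa = a1inv_c(cbar);
      }
      lls[start_idx++] = ll;
      if (ll > best_ll) {
        best_ll = ll;
        best_pm = pm;
        best_kappa = kappa;
        best_conv = converged;
        best_iter = iter;
        if (keep_trace) best_trace = trace;
      }
    }
  }
  // report boundary pm unclamped
  if (best_pm >= 1.0 - 1e-6 - 1e-12) best_pm = 1.0;
  if (best_pm <= 1e-6 + 1e-12) best_pm = 0.0;
  List out = List::create(
    Named("pm") = best_pm, Named("kappa") = best_kappa,
    Named("loglik") = best_ll, Named("converged") = best_conv,
    Named("iter") = best_iter, Named("lls") = lls);
  if (keep_trace) out["trace"] = NumericVector(best_trace.begin(), best_trace.end());
  return out;
}
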