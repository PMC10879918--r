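#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Williams' trend statistic for an "increasing" alternative on one value
// vector laid out group-by-group (control first, then dose groups in
// ascending dose order).  The highest dose's isotonic (PAVA-amalgamated,
// replicate-weighted) mean is compared with the control mean using the
// pooled within-group variance.  Returns +/-Inf when the pooled variance
// vanishes but the means differ, and 0 when everything is constant.
static double williams_stat(const double *x, const int *sizes, int ngroups,
                            std::vector<double> &mean_buf,
                            std::vector<double> &w_buf) {
  int ntot = 0;
  for (int j = 0; j < ngroups; ++j) {
    double s = 0.0;
    for (int i = 0; i < sizes[j]; ++i) s += x[ntot + i];
    mean_buf[j] = s / sizes[j];
    ntot += sizes[j];
  }
  double ss = 0.0;
  int off = 0;
  for (int j = 0; j < ngroups; ++j) {
    for (int i = 0; i < sizes[j]; ++i) {
      double d = x[off + i] - mean_buf[j];
      ss += d * d;
    }
    off += sizes[j];
  }
  int df = ntot - ngroups;
  double s2 = df > 0 ? ss / df : 0.0;

  // weighted PAVA over the dose groups only (indices 1..ngroups-1)
  int K = ngroups - 1;
  std::vector<double> &m = mean_buf;  // reuse: dose means start at m[1]
  for (int j = 0; j < K; ++j) w_buf[j] = (double)sizes[j + 1];
  std::vector<double> pm(K), pw(K);
  int nb = 0;
  for (int j = 0; j < K; ++j) {
    pm[nb] = m[j + 1];
    pw[nb] = w_buf[j];
    ++nb;
    while (nb > 1 && pm[nb - 2] > pm[nb - 1]) {
      double wsum = pw[nb - 2] + pw[nb - 1];
      pm[nb - 2] = (pm[nb - 2] * pw[nb - 2] + pm[nb - 1] * pw[nb - 1]) / wsum;
      pw[nb - 2] = wsum;
      --nb;
    }
  }
  double mu_top = pm[nb - 1];  // amalgamated mean of the highest dose
  double diff = mu_top - mean_buf[0];
  double denom2 = s2 * (1.0 / sizes[ngroups - 1] + 1.0 / sizes[0]);
  if (denom2 <= 0.0) {
    if (std::fabs(diff) < 1e-12) return 0.0;
    return diff > 0 ? R_PosInf : R_NegInf;
  }
  return diff / std::sqrt(denom2);
}

// [[Rcpp::export(name = ".williams_perm_cpp")]]
List williams_perm_cpp(NumericMatrix y, IntegerVector sizes, int n_perm) {
  int ngroups = sizes.size();
  int ntot = 0;
  for (int j = 0; j < ngroups; ++j) {
    if (sizes[j] < 1) stop("group sizes must be >= 1");
    ntot += sizes[j];
  }
  if (y.ncol() != ntot)
    stop("value matrix has %d columns but group sizes sum to %d",
         y.ncol(), ntot);
  if (ngroups < 2) stop("need a control group and at least one dose group");
  int nrow = y.nrow();
  NumericVector stat_up(nrow), stat_dn(nrow), p_up(nrow), p_dn(nrow);
  std::vector<double> x(ntot), neg(ntot), mean_buf(ngroups), w_buf(ngroups);
  RNGScope scope;
  for (int g = 0; g < nrow; ++g) {
    for (int i = 0; i < ntot; ++i) x[i] = y(g, i);
    for (int i = 0; i < ntot; ++i) neg[i] = -x[i];
    double t_up = williams_stat(x.data(), sizes.begin(), ngroups,
                                mean_buf, w_buf);
    double t_dn = williams_stat(neg.data(), sizes.begin(), ngroups,
                                mean_buf, w_buf);
    stat_up[g] = t_up;
    stat_dn[g] = t_dn;
    bool const_up = (t_up == 0.0) && (t_dn == 0.0);
    if (const_up) {  // all group means equal with zero variance
      bool allsame = true;
      for (int i = 1; i < ntot && allsame; ++i)
        if (x[i] != x[0]) allsame = false;
      if (allsame) {
        p_up[g] = 1.0;
        p_dn[g] = 1.0;
        continue;
      }
    }
    if (!R_finite(t_up) || !R_finite(t_dn)) {
      // zero pooled variance with unequal means: permutation bound / cap
      p_up[g] = (t_up == R_PosInf) ? 1.0 / (n_perm + 1.0) : 1.0;
      p_dn[g] = (t_dn == R_PosInf) ? 1.0 / (n_perm + 1.0) : 1.0;
      if (t_up == R_NegInf) p_up[g] = 1.0;
      if (t_dn == R_NegInf) p_dn[g] = 1.0;
      continue;
    }
    int ge_up = 0, ge_dn = 0;
    for (int b = 0; b < n_perm; ++b) {
      for (int i = ntot - 1; i > 0; --i) {  // Fisher-Yates via R's RNG
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        double tmp = x[i]; x[i] = x[j]; x[j] = tmp;
      }
      double tp = williams_stat(x.data(), sizes.begin(), ngroups,
                                mean_buf, w_buf);
      if (tp >= t_up) ++ge_up;
      // down statistic of the permuted data = up statistic on negated values
      for (int i = 0; i < ntot; ++i) neg[i] = -x[i];
      double tn = williams_stat(neg.data(), sizes.begin(), ngroups,
                                mean_buf, w_buf);
      if (tn >= t_dn) ++ge_dn;
    }
    p_up[g] = (1.0 + ge_up) / (n_perm + 1.0);
    p_dn[g] = (1.0 + ge_dn) / (n_perm + 1.0);
  }
  return List::create(_["stat_up"] = stat_up, _["stat_down"] = stat_dn,
                      _["p_up"] = p_up, _["p_down"] = p_dn);
}
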