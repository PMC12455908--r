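// Compiled core of the multivariate-normal engine: the separation-of-
// variables recursion for log box probabilities, the variable-reordering
// Cholesky, and the Gibbs sweeps of the truncated-normal sampler. All tail
// computations run on the log scale so boxes far in the tails keep full
// relative accuracy.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1mexp_(double x) {
  // log(1 - exp(x)) for x <= 0
  if (x == R_NegInf) return 0.0;
  if (x > -M_LN2) return std::log(-std::expm1(x));
  return std::log1p(-std::exp(x));
}

// log(Phi(zhi) - Phi(zlo)), stable in both tails.
static double log_phi_diff_(double zlo, double zhi) {
  double li;
  if (zhi <= 0.0) {
    double le = R::pnorm(zhi, 0.0, 1.0, 1, 1);
    double ld = (zlo == R_NegInf) ? R_NegInf : R::pnorm(zlo, 0.0, 1.0, 1, 1);
    li = le + log1mexp_(ld - le);
  } else if (zlo >= 0.0) {
    double ldc = R::pnorm(zlo, 0.0, 1.0, 0, 1);
    double lec = (zhi == R_PosInf) ? R_NegInf : R::pnorm(zhi, 0.0, 1.0, 0, 1);
    li = ldc + log1mexp_(lec - ldc);
  } else {
    li = std::log(R::pnorm(zhi, 0.0, 1.0, 1, 0) -
                  R::pnorm(zlo, 0.0, 1.0, 1, 0));
  }
  if (std::isnan(li)) li = R_NegInf;
  return li;
}

// Inverse-CDF draw of a standard normal restricted to (zlo, zhi) at uniform
// u, through log probabilities so far tails do not collapse to a bound.
static double trunc_std_normal_(double u, double zlo, double zhi) {
  double y;
  if (zhi <= 0.0) {
    double le = R::pnorm(zhi, 0.0, 1.0, 1, 1);
    double ld = (zlo == R_NegInf) ? R_NegInf : R::pnorm(zlo, 0.0, 1.0, 1, 1);
    double r0 = std::exp(ld - le);
    y = R::qnorm(le + std::log(r0 + u * (1.0 - r0)), 0.0, 1.0, 1, 1);
  } else if (zlo >= 0.0) {
    double ldc = R::pnorm(zlo, 0.0, 1.0, 0, 1);
    double lec = (zhi == R_PosInf) ? R_NegInf : R::pnorm(zhi, 0.0, 1.0, 0, 1);
    double s0 = std::exp(lec - ldc);
    y = R::qnorm(ldc + std::log1p(-u * (1.0 - s0)), 0.0, 1.0, 0, 1);
  } else {
    double d = R::pnorm(zlo, 0.0, 1.0, 1, 0);
    double e = R::pnorm(zhi, 0.0, 1.0, 1, 0);
    double v = d + u * (e - d);
    if (v < 1e-320) v = 1e-320;
    if (v > 1.0 - 1e-16) v = 1.0 - 1e-16;
    y = R::qnorm(v, 0.0, 1.0, 1, 0);
  }
  if (!std::isfinite(y)) {
    double lo = zlo < -38.0 ? -38.0 : zlo;
    double hi = zhi > 38.0 ? 38.0 : zhi;
    y = 0.5 * (lo + hi);
  }
  if (y < -38.0) y = -38.0;
  if (y > 38.0) y = 38.0;
  return y;
}

// Separation-of-variables log-weights: one row of `w` is one lattice point,
// columns are the d-1 uniforms. Returns log of the per-point integrand.
// [[Rcpp::export]]
NumericVector cpp_sov_logweights(const NumericMatrix& L,
                                 const NumericVector& a,
                                 const NumericVector& b,
                                 const NumericMatrix& w) {
  const int d = a.size(), N = w.nrow();
  NumericVector logw(N);
  std::vector<double> y(d > 1 ? d - 1 : 1);
  for (int p = 0; p < N; ++p) {
    double lw = 0.0;
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int k = 0; k < i; ++k) s += L(i, k) * y[k];
      double lii = L(i, i);
      double zlo = (a[i] == R_NegInf) ? R_NegInf : (a[i] - s) / lii;
      double zhi = (b[i] == R_PosInf) ? R_PosInf : (b[i] - s) / lii;
      lw += log_phi_diff_(zlo, zhi);
      if (lw == R_NegInf) break;
      if (i < d - 1) y[i] = trunc_std_normal_(w(p, i), zlo, zhi);
    }
    logw[p] = lw;
  }
  return logw;
}

// Gibson-Glasbey-Elston variable reordering with incremental Cholesky:
// at each pivot choose the remaining variable with the smallest conditional
// interval probability (evaluated at the conditional expectation of the
// previous variables), then extend the Cholesky factor.
// [[Rcpp::export]]
List cpp_reorder_chol(NumericMatrix cov, NumericVector a, NumericVector b) {
  const int d = a.size();
  NumericMatrix C(clone(cov));
  NumericVector aa(clone(a)), bb(clone(b));
  NumericMatrix L(d, d);
  IntegerVector perm(d);
  std::vector<double> y(d), ssq(d, 0.0), sy(d, 0.0);
  for (int i = 0; i < d; ++i) perm[i] = i + 1;
  for (int i = 0; i < d; ++i) {
    // select the pivot among remaining variables
    int jbest = i;
    double pbest = R_PosInf;
    for (int j = i; j < d; ++j) {
      double s2 = C(j, j) - ssq[j];
      double den = std::sqrt(s2 > 1e-300 ? s2 : 1e-300);
      double zlo = (aa[j] == R_NegInf) ? R_NegInf : (aa[j] - sy[j]) / den;
      double zhi = (bb[j] == R_PosInf) ? R_PosInf : (bb[j] - sy[j]) / den;
      double pj = R::pnorm(zhi, 0.0, 1.0, 1, 0) -
                  R::pnorm(zlo, 0.0, 1.0, 1, 0);
      if (pj < pbest) { pbest = pj; jbest = j; }
    }
    if (jbest != i) {
      for (int k = 0; k < d; ++k) std::swap(C(i, k), C(jbest, k));
      for (int k = 0; k < d; ++k) std::swap(C(k, i), C(k, jbest));
      for (int k = 0; k < i; ++k) std::swap(L(i, k), L(jbest, k));
      std::swap(aa[i], aa[jbest]); std::swap(bb[i], bb[jbest]);
      std::swap(perm[i], perm[jbest]);
      std::swap(ssq[i], ssq[jbest]); std::swap(sy[i], sy[jbest]);
    }
    double lkk = C(i, i) - ssq[i];
    if (lkk <= 0.0)
      stop("covariance not positive definite at pivot %d", i + 1);
    double lii = std::sqrt(lkk);
    L(i, i) = lii;
    for (int j = i + 1; j < d; ++j) {
      double cross = 0.0;
      for (int k = 0; k < i; ++k) cross += L(i, k) * L(j, k);
      L(j, i) = (C(j, i) - cross) / lii;
    }
    // conditional expectation of variable i inside its interval
    double zlo = (aa[i] == R_NegInf) ? R_NegInf : (aa[i] - sy[i]) / lii;
    double zhi = (bb[i] == R_PosInf) ? R_PosInf : (bb[i] - sy[i]) / lii;
    double lp = log_phi_diff_(zlo, zhi);
    double dlo = (zlo == R_NegInf) ? 0.0 : R::dnorm(zlo, 0.0, 1.0, 0);
    double dhi = (zhi == R_PosInf) ? 0.0 : R::dnorm(zhi, 0.0, 1.0, 0);
    if (std::isfinite(lp) && lp > -700.0) y[i] = (dlo - dhi) / std::exp(lp);
    else {
      double lo = zlo < -38.0 ? -38.0 : zlo, hi = zhi > 38.0 ? 38.0 : zhi;
      y[i] = 0.5 * (lo + hi);
    }
    for (int j = i + 1; j < d; ++j) {
      ssq[j] += L(j, i) * L(j, i);
      sy[j] += L(j, i) * y[i];
    }
  }
  return List::create(Named("L") = L, Named("a") = aa, Named("b") = bb,
                      Named("perm") = perm);
}

// Parallel-chain Gibbs for the box-truncated multivariate normal. H is the
// precision matrix; chains start from independent draws of the truncated
// marginals and are swept `burn_in` times. Returns the final states.
// [[Rcpp::export]]
NumericMatrix cpp_gibbs_tmvn(const NumericMatrix& H,
                             const NumericVector& mean,
                             const NumericVector& lower,
                             const NumericVector& upper,
                             const NumericVector& sd_marg,
                             int n_chains, int burn_in) {
  const int d = mean.size();
  NumericMatrix Z(n_chains, d);
  std::vector<double> csd(d);
  for (int i = 0; i < d; ++i) csd[i] = 1.0 / std::sqrt(H(i, i));
  // g[c][i] = sum_k H(i,k) * (z_k - mean_k), maintained incrementally
  std::vector<double> g(static_cast<size_t>(n_chains) * d, 0.0);
  for (int c = 0; c < n_chains; ++c) {
    for (int i = 0; i < d; ++i) {
      double zlo = (lower[i] == R_NegInf) ? R_NegInf
                                          : (lower[i] - mean[i]) / sd_marg[i];
      double zhi = (upper[i] == R_PosInf) ? R_PosInf
                                          : (upper[i] - mean[i]) / sd_marg[i];
      Z(c, i) = mean[i] + sd_marg[i] * trunc_std_normal_(R::unif_rand(), zlo, zhi);
    }
    for (int i = 0; i < d; ++i) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) acc += H(i, k) * (Z(c, k) - mean[k]);
      g[static_cast<size_t>(c) * d + i] = acc;
    }
  }
  for (int sweep = 0; sweep < burn_in; ++sweep) {
    for (int c = 0; c < n_chains; ++c) {
      double* gc = &g[static_cast<size_t>(c) * d];
      for (int i = 0; i < d; ++i) {
        double zci = Z(c, i) - mean[i];
        double cmean = mean[i] - (gc[i] - zci * H(i, i)) / H(i, i);
        double zlo = (lower[i] == R_NegInf) ? R_NegInf
                                            : (lower[i] - cmean) / csd[i];
        double zhi = (upper[i] == R_PosInf) ? R_PosInf
                                            : (upper[i] - cmean) / csd[i];
        double znew = cmean + csd[i] * trunc_std_normal_(R::unif_rand(), zlo, zhi);
        double delta = znew - Z(c, i);
        if (delta != 0.0)
          for (int k = 0; k < d; ++k) gc[k] += H(k, i) * delta;
        Z(c, i) = znew;
      }
    }
  }
  return Z;
}
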