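// Exact negative-binomial two-group test, conditional on the total
// pseudo-count Z of each fragment. With both class sums NB-distributed at a
// shared success probability (the null after library equalization), the
// class-A sum given the total follows a beta-binomial law with shape
// parameters alpha = n_A/phi and beta = n_B/phi:
//
//   P(z | Z) = C(Z, z) * B(z + alpha, Z - z + beta) / B(alpha, beta)
//
// The two-sided p-value accumulates all outcomes whose probability does not
// exceed the observed one ("small-p" rejection region). The pmf is
// log-concave in z, so that region is a union of two tails; their
// boundaries are located by binary search around the mode and each tail is
// summed inward by ratio recursion, giving O(tail width) work per fragment
// with a handful of flops per term.

#include <Rcpp.h>
using namespace Rcpp;

struct BetaBinom {
  double Z, alpha, beta, mu1, mu2, lognorm;
  BetaBinom(double Z_, double alpha_, double beta_, double n1, double n2)
    : Z(Z_), alpha(alpha_), beta(beta_) {
    double mu = Z / (n1 + n2);
    mu1 = n1 * mu;
    mu2 = n2 * mu;
    // convolution identity: the two class sums share a success probability,
    // so their total is NB with the summed shape
    lognorm = R::dnbinom_mu(Z, alpha + beta, Z, 1);
  }
  // evaluated through dnbinom for saddle-point accuracy at large shapes,
  // and so that exact ties (the symmetric outcome under equal class sizes)
  // compare exactly as in direct enumeration of the NB product
  double logp(double z) const {
    return R::dnbinom_mu(z, alpha, mu1, 1) +
           R::dnbinom_mu(Z - z, beta, mu2, 1) - lognorm;
  }
  // P(z + 1) / P(z)
  double ratio_up(double z) const {
    return ((z + alpha) / (z + 1.0)) * ((Z - z) / (Z - z - 1.0 + beta));
  }
  // P(z - 1) / P(z)
  double ratio_down(double z) const {
    return (z / (z - 1.0 + alpha)) * ((Z - z + beta) / (Z - z + 1.0));
  }
};

// integer ternary search for the mode of the log-concave pmf
static double find_mode(const BetaBinom &d) {
  double lo = 0.0, hi = d.Z;
  while (hi - lo > 2.0) {
    double m1 = std::floor(lo + (hi - lo) / 3.0);
    double m2 = std::floor(hi - (hi - lo) / 3.0);
    if (m2 <= m1) break;
    if (d.logp(m1) < d.logp(m2)) lo = m1 + 1.0; else hi = m2;
  }
  double mode = lo, best = d.logp(lo);
  for (double z = lo + 1.0; z <= hi; z += 1.0) {
    double v = d.logp(z);
    if (v > best) { best = v; mode = z; }
  }
  return mode;
}

// largest z in [0, mode] with logp(z) <= thr, or -1 when none
static double left_boundary(const BetaBinom &d, double mode, double thr) {
  if (d.logp(0.0) > thr) return -1.0;
  double lo = 0.0, hi = mode;
  while (hi - lo > 0.5) {
    double mid = std::floor((lo + hi) / 2.0 + 0.5);
    if (d.logp(mid) <= thr) lo = mid; else hi = mid - 1.0;
  }
  return lo;
}

// smallest z in [mode, Z] with logp(z) <= thr, or Z + 1 when none
static double right_boundary(const BetaBinom &d, double mode, double thr) {
  if (d.logp(d.Z) > thr) return d.Z + 1.0;
  double lo = mode, hi = d.Z;
  while (hi - lo > 0.5) {
    double mid = std::floor((lo + hi) / 2.0);
    if (d.logp(mid) <= thr) hi = mid; else lo = mid + 1.0;
  }
  return hi;
}

static double pval_one(double z1, double Z, double alpha, double beta,
                       double n1, double n2) {
  BetaBinom d(Z, alpha, beta, n1, n2);
  double lpobs = d.logp(z1);
  double thr = lpobs;
  double mode = find_mode(d);
  if (d.logp(mode) <= thr) return 1.0;  // observed outcome is modal
  double a = left_boundary(d, mode, thr);
  double b = right_boundary(d, mode, thr);
  const double rel_eps = 1e-18;
  double acc = 0.0;
  if (a >= 0.0) {                      // left tail [0, a], summed inward
    double t = std::exp(d.logp(a) - lpobs);
    for (double z = a; z >= 0.0; z -= 1.0) {
      acc += t;
      if (t < rel_eps * acc || z == 0.0) break;
      t *= d.ratio_down(z);
    }
  }
  if (b <= d.Z) {                      // right tail [b, Z], summed inward
    double t = std::exp(d.logp(b) - lpobs);
    for (double z = b; z <= d.Z; z += 1.0) {
      acc += t;
      if (t < rel_eps * acc || z == d.Z) break;
      t *= d.ratio_up(z);
    }
  }
  double p = std::exp(lpobs + std::log(acc));
  return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export]]
NumericVector exact_nb_pvals_cpp(NumericVector s1, NumericVector s2,
                                 double n1, double n2, NumericVector phi) {
  int G = s1.size();
  if (s2.size() != G || phi.size() != G)
    stop("s1, s2 and phi must have equal length");
  NumericVector p(G);
  for (int g = 0; g < G; g++) {
    double z1 = std::floor(s1[g] + 0.5), z2 = std::floor(s2[g] + 0.5);
    double Z = z1 + z2;
    if (Z <= 0.0) { p[g] = 1.0; continue; }
    double ph = phi[g] < 1e-10 ? 1e-10 : phi[g];
    p[g] = pval_one(z1, Z, n1 / ph, n2 / ph, n1, n2);
    if (p[g] > 1.0) p[g] = 1.0;
    if (p[g] <= 0.0) p[g] = std::numeric_limits<double>::min();
  }
  return p;
}
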