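#include <Rcpp.h>
using namespace Rcpp;

// Draw from standard normal truncated below at a.
// Naive rejection when the bound leaves decent mass; Robert's (1995)
// translated-exponential rejection otherwise, which stays exact for
// bounds far beyond +8 where inverse-CDF methods lose precision.
static double rtsnorm_lower(double a) {
  if (a < 0.25) {
    double x;
    do {
      x = norm_rand();
    } while (x <= a);
    return x;
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(unif_rand()) / lambda;
    double d = x - lambda;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

// One Gibbs sweep over the latent utilities W (n trees x P taxa).
// For tree j with observed taxon y: W[j,y] ~ N(alpha[cell,y],1) truncated
// below at max_{p!=y} W[j,p]; then each W[j,p], p != y, ~ N(alpha[cell,p],1)
// truncated above at the new W[j,y]. Uses R's RNG stream.
// [[Rcpp::export]]
NumericMatrix cpp_update_W(NumericMatrix W, IntegerVector cell,
                           IntegerVector taxon, NumericMatrix alpha) {
  const int n = W.nrow(), P = W.ncol();
  NumericMatrix out = clone(W);
  for (int j = 0; j < n; ++j) {
    const int y = taxon[j] - 1;
    const int ci = cell[j] - 1;
    double lower = R_NegInf;
    for (int p = 0; p < P; ++p) {
      if (p != y && out(j, p) > lower) lower = out(j, p);
    }
    const double muy = alpha(ci, y);
    const double wy = muy + rtsnorm_lower(lower - muy);
    out(j, y) = wy;
    for (int p = 0; p < P; ++p) {
      if (p == y) continue;
      const double mup = alpha(ci, p);
      out(j, p) = mup - rtsnorm_lower(mup - wy);
    }
  }
  return out;
}

// Monte Carlo integration of the composition simplex: for each cell draw
// n_mc iid N(alpha[cell,], I) utility vectors and tabulate how often each
// taxon attains the maximum. Ties (measure zero) go to the lowest index.
// [[Rcpp::export]]
NumericMatrix cpp_mc_theta(NumericMatrix alpha, int n_mc) {
  const int m = alpha.nrow(), P = alpha.ncol();
  NumericMatrix theta(m, P);
  std::vector<double> w(P);
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < n_mc; ++t) {
      int amax = 0;
      double best = R_NegInf;
      for (int p = 0; p < P; ++p) {
        double wp = alpha(i, p) + norm_rand();
        if (wp > best) {
          best = wp;
          amax = p;
        }
      }
      theta(i, amax) += 1.0;
    }
    for (int p = 0; p < P; ++p) theta(i, p) /= n_mc;
  }
  return theta;
}
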