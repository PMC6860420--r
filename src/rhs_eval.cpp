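#include <Rcpp.h>
using namespace Rcpp;

// Evaluate the network right-hand side for one state vector.
// Reactions are pre-flattened in R (see assemble_rhs): per-reaction kind,
// parameter indices, reactant/product index+coefficient slices and modifier
// slices. Negative state entries are clamped to zero for rate evaluation
// (mass-action positivity guard); buffered species get derivative zero.
//
// kind codes: 0 mass-action irreversible, 1 mass-action reversible,
//             2 hill activation, 3 hill inhibition.
// [[Rcpp::export]]
NumericVector mp_rhs_eval(NumericVector y, NumericVector p,
                          IntegerVector kind, IntegerMatrix pidx,
                          IntegerVector r_off, IntegerVector r_idx,
                          NumericVector r_coef,
                          IntegerVector pr_off, IntegerVector pr_idx,
                          NumericVector pr_coef,
                          IntegerVector m_off, IntegerVector m_idx,
                          LogicalVector buffered) {
  const int ns = y.size(), nr = kind.size();
  std::vector<double> yc(ns);
  for (int i = 0; i < ns; ++i) yc[i] = y[i] > 0 ? y[i] : 0.0;
  NumericVector dy(ns);

  for (int j = 0; j < nr; ++j) {
    double v = 0.0;
    const int k = kind[j];
    if (k == 0 || k == 1) {
      double fwd = p[pidx(j, 0)];
      for (int a = r_off[j]; a < r_off[j + 1]; ++a) {
        double x = yc[r_idx[a]], c = r_coef[a];
        fwd *= (c == 1.0) ? x : std::pow(x, c);
      }
      v = fwd;
      if (k == 1) {
        double rev = p[pidx(j, 1)];
        for (int a = pr_off[j]; a < pr_off[j + 1]; ++a) {
          double x = yc[pr_idx[a]], c = pr_coef[a];
          rev *= (c == 1.0) ? x : std::pow(x, c);
        }
        v -= rev;
      }
      for (int a = m_off[j]; a < m_off[j + 1]; ++a) v *= yc[m_idx[a]];
    } else {
      // Hill: first modifier is the regulator X, remaining multiply.
      double vmax = p[pidx(j, 0)], K = p[pidx(j, 1)];
      double n = pidx(j, 2) >= 0 ? p[pidx(j, 2)] : 1.0;
      double X = yc[m_idx[m_off[j]]];
      double Xn = (n == 1.0) ? X : std::pow(X, n);
      double Kn = (n == 1.0) ? K : std::pow(K, n);
      double denom = Kn + Xn;
      double frac = denom > 0 ? ((k == 2) ? Xn / denom : Kn / denom)
                              : ((k == 2) ? 0.0 : 1.0);
      v = vmax * frac;
      for (int a = m_off[j] + 1; a < m_off[j + 1]; ++a) v *= yc[m_idx[a]];
      for (int a = r_off[j]; a < r_off[j + 1]; ++a) {
        double x = yc[r_idx[a]], c = r_coef[a];
        v *= (c == 1.0) ? x : std::pow(x, c);
      }
    }
    for (int a = r_off[j]; a < r_off[j + 1]; ++a)
      dy[r_idx[a]] -= r_coef[a] * v;
    for (int a = pr_off[j]; a < pr_off[j + 1]; ++a)
      dy[pr_idx[a]] += pr_coef[a] * v;
  }
  for (int i = 0; i < ns; ++i) if (buffered[i]) dy[i] = 0.0;
  return dy;
}
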