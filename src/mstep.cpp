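#include <Rcpp.h>
using namespace Rcpp;

// log(1 - plogis(x)), stable for any x
static inline double log1m_logistic(double x) {
  double ax = std::fabs(x);
  return -0.5 * (x + ax) - std::log1p(std::exp(-ax));
}

// Projected-Newton maximization of the expected complete-data
// log-likelihood of one 2PL item over the quadrature, with backtracking so
// the objective never decreases and box projection to the bounds.
// nik, rik: items x nodes expected counts from the E-step.
// [[Rcpp::export(name = ".mstep_cpp")]]
List mstep_cpp(NumericVector a, NumericVector d,
               NumericMatrix nik, NumericMatrix rik,
               NumericVector nodes,
               double a_lo, double a_hi, double d_lo, double d_hi,
               int max_inner) {
  const int nI = a.size(), K = nodes.size();
  NumericVector an(clone(a)), dn(clone(d));
  for (int i = 0; i < nI; ++i) {
    double ai = an[i], di = dn[i];
    // linear-term coefficients: q = a*rn + d*rs + sum(nik * log(1-P))
    double rn = 0.0, rs = 0.0;
    for (int k = 0; k < K; ++k) {
      rn += rik(i, k) * nodes[k];
      rs += rik(i, k);
    }
    double q = ai * rn + di * rs;
    for (int k = 0; k < K; ++k)
      q += nik(i, k) * log1m_logistic(ai * nodes[k] + di);
    for (int inner = 0; inner < max_inner; ++inner) {
      double ga = rn, gd = rs, haa = 0.0, had = 0.0, hdd = 0.0;
      for (int k = 0; k < K; ++k) {
        double lin = ai * nodes[k] + di;
        double p = 1.0 / (1.0 + std::exp(-lin));
        double np = nik(i, k) * p;
        ga -= np * nodes[k];
        gd -= np;
        double w = np * (1.0 - p);
        haa += w * nodes[k] * nodes[k];
        had += w * nodes[k];
        hdd += w;
      }
      double det = haa * hdd - had * had;
      double da, dd;
      if (R_finite(det) && det > 1e-12) {
        da = (hdd * ga - had * gd) / det;
        dd = (haa * gd - had * ga) / det;
      } else {
        da = ga / std::max(haa, 1e-8);
        dd = gd / std::max(hdd, 1e-8);
      }
      double step = 1.0;
      bool accepted = false;
      for (int t = 0; t < 30; ++t) {
        double ac = std::min(std::max(ai + step * da, a_lo), a_hi);
        double dc = std::min(std::max(di + step * dd, d_lo), d_hi);
        double qc = ac * rn + dc * rs;
        for (int k = 0; k < K; ++k)
          qc += nik(i, k) * log1m_logistic(ac * nodes[k] + dc);
        if (R_finite(qc) && qc >= q - 1e-12) {
          double moved = std::fabs(ac - ai) + std::fabs(dc - di);
          ai = ac; di = dc; q = qc;
          accepted = moved > 1e-10;
          break;
        }
        step *= 0.5;
      }
      if (!accepted) break;
    }
    an[i] = ai; dn[i] = di;
  }
  return List::create(Named("a") = an, Named("d") = dn);
}
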