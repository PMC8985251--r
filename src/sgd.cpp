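#include <Rcpp.h>
using namespace Rcpp;

// One stochastic-gradient epoch over the cells listed in `order`
// (1-based linear indices into the |M| x |D| matrix, column-major).
// Updates DLF (|D| x F) and MLF (|M| x F) in place with the descent step
//   row += alpha * (2 * err * other_row - lambda * row)
// where err = MDR[m,d] - <DLF[d,], MLF[m,]>.
// Returns false if any update produced a non-finite value (divergence).
// [[Rcpp::export(name = ".sgd_epoch")]]
bool sgd_epoch(const NumericMatrix& MDR, NumericMatrix DLF, NumericMatrix MLF,
               const IntegerVector& order, double alpha, double lambda) {
  const int M = MDR.nrow();
  const int F = DLF.ncol();
  for (int t = 0; t < order.size(); ++t) {
    const int cell = order[t] - 1;
    const int m = cell % M;
    const int d = cell / M;
    double pred = 0.0;
    for (int f = 0; f < F; ++f) pred += DLF(d, f) * MLF(m, f);
    const double err = MDR(m, d) - pred;
    for (int f = 0; f < F; ++f) {
      const double dlf = DLF(d, f), mlf = MLF(m, f);
      DLF(d, f) += alpha * (2.0 * err * mlf - lambda * dlf);
      MLF(m, f) += alpha * (2.0 * err * dlf - lambda * mlf);
      if (!std::isfinite(DLF(d, f)) || !std::isfinite(MLF(m, f))) return false;
    }
  }
  return true;
}
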