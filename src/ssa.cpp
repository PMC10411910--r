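#include <Rcpp.h>
using namespace Rcpp;

// Direct-method SSA for first-order conversion networks:
// propensity_j = rate_j * x[reactant_j].
//
// Runs one realization per row of `rates` (cells may differ in their rate
// constants, e.g. for size-scaled transcription) from `init` to `t_end`
// and returns the final state of each cell. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix ssa_ensemble_cpp(IntegerVector reactant0, IntegerMatrix stoich,
                               NumericMatrix rates, IntegerVector init,
                               double t_end) {
  const int nsp = stoich.nrow();
  const int nrxn = stoich.ncol();
  const int ncell = rates.nrow();
  if (reactant0.size() != nrxn || rates.ncol() != nrxn ||
      init.size() != nsp)
    stop("inconsistent network dimensions");
  IntegerMatrix out(ncell, nsp);
  std::vector<int> x(nsp);
  std::vector<double> a(nrxn);
  for (int c = 0; c < ncell; ++c) {
    for (int i = 0; i < nsp; ++i) x[i] = init[i];
    double t = 0.0;
    for (;;) {
      double atot = 0.0;
      for (int j = 0; j < nrxn; ++j) {
        a[j] = rates(c, j) * x[reactant0[j]];
        atot += a[j];
      }
      if (atot <= 0.0) break;
      t += R::exp_rand() / atot;
      if (t > t_end) break;
      double u = unif_rand() * atot;
      double cum = 0.0;
      int j = 0;
      for (; j < nrxn - 1; ++j) {
        cum += a[j];
        if (u < cum) break;
      }
      for (int i = 0; i < nsp; ++i) x[i] += stoich(i, j);
    }
    for (int i = 0; i < nsp; ++i) out(c, i) = x[i];
    if ((c & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
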