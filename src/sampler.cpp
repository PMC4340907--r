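#include <Rcpp.h>
using namespace Rcpp;

// Sequential sampler for the kinetic Ising model.
//
// Given per-cell external fields h (n_cells x T) and couplings J
// (J(i, j) = influence of cell j at time t on cell i at time t + 1),
// draws S(t) column by column:
//   P(S_i(t) = +1 | S(t-1)) = 1 / (1 + exp(-2 * H_i(t-1))),
//   H_i(t-1) = h_i(t-1) + sum_j J_ij S_j(t-1).
// S(1) is drawn from the field alone (uniform when h = 0). Uses R's RNG,
// so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".sample_ki_cpp")]]
IntegerMatrix sample_ki_cpp(NumericMatrix h, NumericMatrix J) {
  const int n = h.nrow(), T = h.ncol();
  if (J.nrow() != n || J.ncol() != n)
    stop("J must be %d x %d to match the field matrix", n, n);
  IntegerMatrix S(n, T);
  std::vector<double> prev(n);
  for (int i = 0; i < n; ++i) {
    double p = 1.0 / (1.0 + std::exp(-2.0 * h(i, 0)));
    S(i, 0) = (unif_rand() < p) ? 1 : -1;
    prev[i] = S(i, 0);
  }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double H = h(i, t - 1);
      for (int j = 0; j < n; ++j) H += J(i, j) * prev[j];
      double p = 1.0 / (1.0 + std::exp(-2.0 * H));
      S(i, t) = (unif_rand() < p) ? 1 : -1;
    }
    for (int i = 0; i < n; ++i) prev[i] = S(i, t);
  }
  return S;
}
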