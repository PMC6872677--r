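#include <Rcpp.h>
using namespace Rcpp;

// Between-community mean nearest taxon distance (betaMNTD) for every sample
// pair under a set of tip-label permutations of the patristic matrix.
//
// pd:      K x K patristic distance matrix
// taxa:    list of integer vectors (0-based) of taxa present per sample
// weights: list of numeric vectors, relative abundance (or 1/richness for
//          the unweighted variant) aligned with taxa
// perms:   P x K integer matrix (0-based); each row maps original taxon
//          index -> shuffled tip position. Row 0 is usually the identity
//          (the observed value).
//
// Returns an n_pairs x P matrix of betaMNTD values; pairs are ordered
// (0,1),(0,2),...,(1,2),... matching R's lower-triangle dist ordering by
// columns: here we emit pair (i,j), i<j in row-major order and the R side
// maps them.
// [[Rcpp::export]]
NumericMatrix bmntd_perm_cpp(const NumericMatrix& pd, const List& taxa,
                             const List& weights, const IntegerMatrix& perms) {
  const int n = taxa.size();
  const int K = pd.nrow();
  const int P = perms.nrow();
  const int n_pairs = n * (n - 1) / 2;
  NumericMatrix out(n_pairs, P);

  std::vector<std::vector<int>> idx(n);
  std::vector<std::vector<double>> wts(n);
  for (int s = 0; s < n; ++s) {
    idx[s] = as<std::vector<int>>(taxa[s]);
    wts[s] = as<std::vector<double>>(weights[s]);
  }

  // M[i][s]: for the current permutation, min patristic distance from
  // (mapped) taxon i to sample s's (mapped) member set
  std::vector<double> M((size_t)K * n);

  for (int p = 0; p < P; ++p) {
    IntegerMatrix::ConstRow pr = perms(p, _);
    for (int s = 0; s < n; ++s) {
      const std::vector<int>& js = idx[s];
      const int ns = js.size();
      for (int i = 0; i < K; ++i) {
        const double* row = &pd(0, pr[i]); // column pointer (pd symmetric)
        double mn = R_PosInf;
        for (int jj = 0; jj < ns; ++jj) {
          const double v = row[pr[js[jj]]];
          if (v < mn) mn = v;
        }
        M[(size_t)i * n + s] = mn;
      }
    }
    int pair = 0;
    for (int a = 0; a < n - 1; ++a) {
      for (int b = a + 1; b < n; ++b, ++pair) {
        double sa = 0.0, sb = 0.0;
        const std::vector<int>& ia = idx[a];
        const std::vector<double>& wa = wts[a];
        for (size_t t = 0; t < ia.size(); ++t)
          sa += wa[t] * M[(size_t)ia[t] * n + b];
        const std::vector<int>& ib = idx[b];
        const std::vector<double>& wb = wts[b];
        for (size_t t = 0; t < ib.size(); ++t)
          sb += wb[t] * M[(size_t)ib[t] * n + a];
        out(pair, p) = 0.5 * (sa + sb);
      }
    }
  }
  return out;
}
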