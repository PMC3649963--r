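#include <Rcpp.h>
using namespace Rcpp;

// Simulate a first-order Markov chain over states 1..k.
// trans: k x k row-stochastic transition matrix; init: length-k start distribution.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export(name = ".markov_chain")]]
IntegerVector markov_chain(int n, NumericMatrix trans, NumericVector init) {
  int k = trans.nrow();
  if (trans.ncol() != k || init.size() != k)
    stop("transition matrix must be square and match the start distribution");
  IntegerVector out(n);
  if (n == 0) return out;
  // cumulative rows
  NumericMatrix cum(k, k);
  for (int i = 0; i < k; ++i) {
    double acc = 0.0;
    for (int j = 0; j < k; ++j) { acc += trans(i, j); cum(i, j) = acc; }
    if (cum(i, k - 1) <= 0) stop("transition row sums to zero");
    for (int j = 0; j < k; ++j) cum(i, j) /= cum(i, k - 1);
  }
  NumericVector cinit(k);
  double acc = 0.0;
  for (int j = 0; j < k; ++j) { acc += init[j]; cinit[j] = acc; }
  for (int j = 0; j < k; ++j) cinit[j] /= acc;

  RNGScope scope;
  double u = unif_rand();
  int s = 0;
  while (s < k - 1 && u > cinit[s]) ++s;
  out[0] = s + 1;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int t = 0;
    while (t < k - 1 && u > cum(s, t)) ++t;
    out[i] = t + 1;
    s = t;
  }
  return out;
}
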