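#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-1 Markov chain over the 4 nucleotide states.
// cum: 4x4 row-wise cumulative transition probabilities (last column == 1).
// u: n uniforms drawn from R's RNG so the chain is reproducible under
//    set.seed() and uses no RNG state of its own.
// Returns 1-based state indices (1=A, 2=C, 3=G, 4=T).
// [[Rcpp::export]]
IntegerVector markov_chain_states(int n, NumericMatrix cum, NumericVector u) {
  if (n < 1) stop("n must be >= 1");
  if (cum.nrow() != 4 || cum.ncol() != 4) stop("cum must be 4x4");
  if (u.size() < n) stop("need n uniforms");
  IntegerVector s(n);
  double x = u[0];
  int prev = x < 0.25 ? 0 : (x < 0.5 ? 1 : (x < 0.75 ? 2 : 3));
  s[0] = prev + 1;
  for (int i = 1; i < n; ++i) {
    x = u[i];
    int k = 0;
    while (k < 3 && x > cum(prev, k)) ++k;
    s[i] = k + 1;
    prev = k;
  }
  return s;
}
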