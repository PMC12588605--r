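#include <Rcpp.h>
using namespace Rcpp;

// Batch Fisher-Yates permutations using R's RNG stream, so results are
// reproducible under set.seed(). Returns an n x k matrix whose columns are
// independent uniform random permutations of 1..n.
// [[Rcpp::export]]
IntegerMatrix batch_permutations(int n, int k) {
  if (n < 1 || k < 0) stop("n must be >= 1 and k >= 0");
  IntegerMatrix M(n, k);
  for (int j = 0; j < k; ++j) {
    int *col = &M(0, j);
    for (int i = 0; i < n; ++i) col[i] = i + 1;
    for (int i = n - 1; i > 0; --i) {
      int r = (int)(unif_rand() * (i + 1));
      if (r > i) r = i; // guard against unif_rand() == 1.0
      int tmp = col[i];
      col[i] = col[r];
      col[r] = tmp;
    }
  }
  return M;
}
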