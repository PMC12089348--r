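#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard (curveball-style) swaps on a binary matrix, preserving
// every row and column sum.  Each attempt draws two distinct rows and
// two distinct columns with R's RNG (so results are reproducible under
// set.seed) and, when the 2x2 submatrix is a checkerboard, flips it.
// nswaps counts attempts, successful or not.
// [[Rcpp::export]]
IntegerMatrix checkerboard_swaps(IntegerMatrix mat, int nswaps) {
  IntegerMatrix m = clone(mat);
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  RNGScope scope;
  for (int s = 0; s < nswaps; ++s) {
    int i1 = (int)(unif_rand() * nr);
    int i2 = (int)(unif_rand() * (nr - 1));
    if (i2 >= i1) ++i2;
    int j1 = (int)(unif_rand() * nc);
    int j2 = (int)(unif_rand() * (nc - 1));
    if (j2 >= j1) ++j2;
    const int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      m(i1, j1) = 0; m(i2, j2) = 0; m(i1, j2) = 1; m(i2, j1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      m(i1, j1) = 1; m(i2, j2) = 1; m(i1, j2) = 0; m(i2, j1) = 0;
    }
  }
  return m;
}
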