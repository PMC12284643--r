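#include <Rcpp.h>
using namespace Rcpp;

// symmetric (half-sample mirror) boundary index
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D correlation of `img` with `ker` (odd dimensions), reflect padding.
// `want` (same size as img, optional) restricts the output pixels computed;
// others are left at 0.
// [[Rcpp::export(name = ".conv2_reflect")]]
NumericMatrix conv2_reflect(NumericMatrix img, NumericMatrix ker,
                            Nullable<LogicalMatrix> want = R_NilValue) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = ker.nrow(), kc = ker.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int rr = kr / 2, rc = kc / 2;
  LogicalMatrix msk;
  bool masked = want.isNotNull();
  if (masked) msk = LogicalMatrix(want);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (masked && !msk(i, j)) continue;
      double acc = 0;
      for (int b = -rc; b <= rc; ++b) {
        int jj = reflect(j + b, nc);
        for (int a = -rr; a <= rr; ++a) {
          int ii = reflect(i + a, nr);
          acc += img(ii, jj) * ker(a + rr, b + rc);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
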