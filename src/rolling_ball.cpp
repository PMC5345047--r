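#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat ball structuring element.
// offsets (dy, dx) enumerate the ball support; h is the ball height at each
// offset (gray levels). Pixels whose offset falls outside the frame are
// ignored (min/max over the valid support only), which reproduces padding
// with +Inf (erosion) / -Inf (dilation). The loop is offset-outer so each
// pass streams contiguous columns, letting the compiler vectorize.
// [[Rcpp::export]]
NumericMatrix ball_transform_cpp(const NumericMatrix& img,
                                 const IntegerVector& dy,
                                 const IntegerVector& dx,
                                 const NumericVector& h,
                                 const bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), K = dy.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int k = 0; k < K; ++k) {
    const int oy = dy[k], ox = dx[k];
    const double hk = h[k];
    const int i0 = std::max(0, -oy), i1 = std::min(nr, nr - oy);
    const int j0 = std::max(0, -ox), j1 = std::min(nc, nc - ox);
    if (i0 >= i1 || j0 >= j1) continue;
    const int len = i1 - i0;
    for (int j = j0; j < j1; ++j) {
      const double* s = src + (size_t)(j + ox) * nr + (i0 + oy);
      double* d = dst + (size_t)j * nr + i0;
      if (erode) {
        for (int i = 0; i < len; ++i) {
          const double v = s[i] - hk;
          if (v < d[i]) d[i] = v;
        }
      } else {
        for (int i = 0; i < len; ++i) {
          const double v = s[i] + hk;
          if (v > d[i]) d[i] = v;
        }
      }
    }
  }
  return out;
}
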