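// Compiled kernels for the image-processing hot paths: grayscale
// morphology with a non-flat (ball) structuring element, local-mean
// filtering, and separable convolution. All functions take an image
// already padded by the caller (who chooses the border policy) and return
// the valid core of size h x w.

#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element given by offsets
// (dr, dc) and heights hgt: out(x) = min_y img(x + y) - hgt(y).
// `pad` must be padded by max(|dr|, |dc|) with +Inf-like values.
// [[Rcpp::export]]
NumericMatrix erode_nonflat_cpp(NumericMatrix pad, IntegerVector dr,
                                IntegerVector dc, NumericVector hgt,
                                int r, int h, int w) {
  NumericMatrix out(h, w);
  std::fill(out.begin(), out.end(), R_PosInf);
  int nh = pad.nrow();
  const double* p = pad.begin();
  double* o = out.begin();
  for (int k = 0; k < dr.size(); ++k) {
    const double* src = p + (size_t)(r + dc[k]) * nh + (r + dr[k]);
    double b = hgt[k];
    for (int j = 0; j < w; ++j) {
      const double* col = src + (size_t)j * nh;
      double* ocol = o + (size_t)j * h;
      for (int i = 0; i < h; ++i) {
        double v = col[i] - b;
        if (v < ocol[i]) ocol[i] = v;
      }
    }
  }
  return out;
}

// Sum over the local neighborhood whose half-width in columns at row
// offset dr is hw[dr + r] (hw < 0 marks an excluded row), i.e. a disk or
// square depending on hw. `pad` must be reflect-padded by r.
// [[Rcpp::export]]
NumericMatrix local_sum_cpp(NumericMatrix pad, IntegerVector hw,
                            int r, int h, int w) {
  int nh = pad.nrow(), nw = pad.ncol();
  // prefix sums along columns for each row: P(i, j) = sum_{c <= j} pad(i, c)
  std::vector<double> P((size_t)nh * (nw + 1), 0.0);
  for (int j = 0; j < nw; ++j)
    for (int i = 0; i < nh; ++i)
      P[(size_t)(j + 1) * nh + i] = P[(size_t)j * nh + i] + pad(i, j);
  NumericMatrix out(h, w);
  for (int k = 0; k < hw.size(); ++k) {
    int d = k - r;
    int half = hw[k];
    if (half < 0) continue;
    for (int j = 0; j < w; ++j) {
      // window columns in padded coords: [j + r - half, j + r + half]
      const double* hi = &P[(size_t)(j + r + half + 1) * nh];
      const double* lo = &P[(size_t)(j + r - half) * nh];
      for (int i = 0; i < h; ++i) {
        out(i, j) += hi[i + r + d] - lo[i + r + d];
      }
    }
  }
  return out;
}
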