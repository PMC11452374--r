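#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat structuring element given as
// offset lists (dr, dc) and per-offset heights h. Used by the rolling-ball
// background estimator. Out-of-image offsets are skipped, so the border is
// handled by the reduced neighbourhood. Loops run offset-outer over the
// valid subregion so the inner loop is a contiguous column sweep.

static NumericMatrix gray_morph(const NumericMatrix& img,
                                const IntegerVector& dr,
                                const IntegerVector& dc,
                                const NumericVector& h,
                                const bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int k = 0; k < K; ++k) {
    const int a = dr[k], b = dc[k];
    const double hk = erode ? h[k] : -h[k];
    const int i0 = std::max(0, -a), i1 = std::min(nr, nr - a);
    const int j0 = std::max(0, -b), j1 = std::min(nc, nc - b);
    for (int j = j0; j < j1; ++j) {
      const double* s = src + (size_t)(j + b) * nr + (i0 + a);
      double* d = dst + (size_t)j * nr + i0;
      const int n = i1 - i0;
      if (erode) {
        for (int i = 0; i < n; ++i) {
          const double v = s[i] - hk;
          if (v < d[i]) d[i] = v;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          const double v = s[i] - hk;  // hk already negated: v = s + h
          if (v > d[i]) d[i] = v;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gray_erode")]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dr,
                             const IntegerVector& dc,
                             const NumericVector& h) {
  return gray_morph(img, dr, dc, h, true);
}

// [[Rcpp::export(name = ".cpp_gray_dilate")]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dr,
                              const IntegerVector& dc,
                              const NumericVector& h) {
  return gray_morph(img, dr, dc, h, false);
}

// 8-connected component labelling of a binary image (foreground != 0),
// iterative flood fill; labels assigned in raster order.

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(const NumericMatrix& bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (bin(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (bin(qi, qj) == 0 || lab(qi, qj) != 0) continue;
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
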