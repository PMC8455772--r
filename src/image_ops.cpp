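// Bilinear affine sampling: the one kernel behind resampling, crop
// extraction and augmentation warps. Out-of-bounds source positions are
// zero-filled. Source position for output pixel (i, j):
//   y = ay + i * by ,  x = ax + j * bx
// with (y, x) in 0-based pixel-center coordinates of the source grid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double sample_bilinear(const arma::mat& img, double y, double x) {
  const int h = img.n_rows, w = img.n_cols;
  if (y <= -1.0 || x <= -1.0 || y >= h || x >= w) return 0.0;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  double fy = y - y0, fx = x - x0;
  double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
  bool y0i = y0 >= 0 && y0 < h, y1i = y0 + 1 >= 0 && y0 + 1 < h;
  bool x0i = x0 >= 0 && x0 < w, x1i = x0 + 1 >= 0 && x0 + 1 < w;
  if (y0i && x0i) v00 = img(y0, x0);
  if (y0i && x1i) v01 = img(y0, x0 + 1);
  if (y1i && x0i) v10 = img(y0 + 1, x0);
  if (y1i && x1i) v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// max_y / max_x (when >= 0) clamp the source position from above: used by
// the pad+resample path so a sub-pixel overshoot past the padded canvas
// edge does not bleed zero into the border.
// [[Rcpp::export]]
arma::mat cpp_affine_sample(const arma::mat& img, int out_h, int out_w,
                            double ay, double by, double ax, double bx,
                            double max_y = -1.0, double max_x = -1.0) {
  arma::mat out(out_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    double x = ax + j * bx;
    if (max_x >= 0 && x > max_x) x = max_x;
    for (int i = 0; i < out_h; ++i) {
      double y = ay + i * by;
      if (max_y >= 0 && y > max_y) y = max_y;
      out(i, j) = sample_bilinear(img, y, x);
    }
  }
  return out;
}
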