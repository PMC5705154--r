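#include <Rcpp.h>
using namespace Rcpp;

// Reflect an index into [0, n-1] (symmetric padding, edge pixel repeated:
// ... c b a | a b c ... | c b a ...). Matches the reflect rule used for the
// Sobel border handling on the R side.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Bilinear sample of a matrix at continuous (x, y). The matrix uses the
// bottom-left-origin convention: value at integer pixel (x, y) is
// m(y, x) with 0-based indices, row 0 = bottom image row.
static inline double bilinear_at(const NumericMatrix& m, double x, double y) {
  int nx = m.ncol(), ny = m.nrow();
  double fx = std::floor(x), fy = std::floor(y);
  double tx = x - fx, ty = y - fy;
  int x0 = reflect_index((int)fx,     nx);
  int x1 = reflect_index((int)fx + 1, nx);
  int y0 = reflect_index((int)fy,     ny);
  int y1 = reflect_index((int)fy + 1, ny);
  double v00 = m(y0, x0), v10 = m(y0, x1), v01 = m(y1, x0), v11 = m(y1, x1);
  return (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11);
}

//' @noRd
// [[Rcpp::export(name = ".bilinear_sample")]]
NumericVector bilinear_sample_cpp(NumericMatrix m, NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bilinear_at(m, x[i], y[i]);
  return out;
}

// Mean squared edge difference for a batch of candidate poses.
// exr/eyr: reference edge values at the (possibly clipped) template pixels;
// offx/offy: template pixel offsets relative to the template centre;
// cx/cy: current centre about which the pose rotates/shifts;
// poses: matrix with columns (shift_x, shift_y, theta_radians).
// The bilinear weights are computed once per pixel and shared between the
// two edge images; samples fully inside the image skip the reflect logic.
//' @noRd
// [[Rcpp::export(name = ".pose_ssd_batch")]]
NumericVector pose_ssd_batch_cpp(NumericMatrix ex_cur, NumericMatrix ey_cur,
                                 NumericVector exr, NumericVector eyr,
                                 NumericVector offx, NumericVector offy,
                                 double cx, double cy, NumericMatrix poses) {
  int npx = offx.size();
  int np = poses.nrow();
  int nx = ex_cur.ncol(), ny = ex_cur.nrow();
  const double *ex = ex_cur.begin(), *ey = ey_cur.begin();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double sx = poses(p, 0), sy = poses(p, 1), th = poses(p, 2);
    double ct = std::cos(th), st = std::sin(th);
    double acc = 0.0;
    for (int k = 0; k < npx; ++k) {
      double x = cx + ct * offx[k] - st * offy[k] + sx;
      double y = cy + st * offx[k] + ct * offy[k] + sy;
      double fx = std::floor(x), fy = std::floor(y);
      double tx = x - fx, ty = y - fy;
      int x0 = (int)fx, y0 = (int)fy, x1 = x0 + 1, y1 = y0 + 1;
      if (x0 < 0 || x1 >= nx || y0 < 0 || y1 >= ny) {
        x0 = reflect_index(x0, nx); x1 = reflect_index(x1, nx);
        y0 = reflect_index(y0, ny); y1 = reflect_index(y1, ny);
      }
      double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty);
      double w01 = (1 - tx) * ty, w11 = tx * ty;
      int i00 = y0 + ny * x0, i10 = y0 + ny * x1;
      int i01 = y1 + ny * x0, i11 = y1 + ny * x1;
      double dx = exr[k] - (w00 * ex[i00] + w10 * ex[i10] +
                            w01 * ex[i01] + w11 * ex[i11]);
      double dy = eyr[k] - (w00 * ey[i00] + w10 * ey[i10] +
                            w01 * ey[i01] + w11 * ey[i11]);
      acc += dx * dx + dy * dy;
    }
    out[p] = acc / npx;
  }
  return out;
}
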