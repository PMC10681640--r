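#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian smoothing of a square matrix (reflective borders are not
// needed for the cost: truncation at the frame edge is applied identically to
// subject and reference, so the comparison stays fair).
// [[Rcpp::export]]
NumericMatrix cpp_smooth2d(const NumericMatrix& m, const NumericVector& kernel) {
  const int nr = m.nrow(), nc = m.ncol();
  const int r = (kernel.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* pm = m.begin();
  const double* pk = kernel.begin();
  double* pt = tmp.begin();
  double* po = out.begin();
  // along rows (T1 axis): columns are contiguous
  for (int j = 0; j < nc; ++j) {
    const double* col = pm + (size_t)j * nr;
    double* tcol = pt + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      const int lo = std::max(0, i - r), hi = std::min(nr - 1, i + r);
      for (int k = lo; k <= hi; ++k) acc += col[k] * pk[k - i + r];
      tcol[i] = acc;
    }
  }
  // along columns (FLAIR axis): accumulate shifted columns, cache-friendly
  for (int j = 0; j < nc; ++j) {
    double* ocol = po + (size_t)j * nr;
    const int lo = std::max(0, j - r), hi = std::min(nc - 1, j + r);
    for (int k = lo; k <= hi; ++k) {
      const double w = pk[k - j + r];
      const double* tcol = pt + (size_t)k * nr;
      for (int i = 0; i < nr; ++i) ocol[i] += tcol[i] * w;
    }
  }
  return out;
}

// Bin weighted intensity points onto a uniform bins x bins frame, clipping
// out-of-range points into the edge bins (mass conservation).
// [[Rcpp::export]]
NumericMatrix cpp_bin_points(const NumericMatrix& pts, const NumericVector& w,
                             double t1_lo, double t1_step,
                             double f_lo, double f_step, int bins) {
  NumericMatrix H(bins, bins);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((pts(i, 0) - t1_lo) / t1_step);
    int iy = (int)std::floor((pts(i, 1) - f_lo) / f_step);
    ix = std::min(std::max(ix, 0), bins - 1);
    iy = std::min(std::max(iy, 0), bins - 1);
    H(ix, iy) += w[i];
  }
  return H;
}

// Registration cost: transform weighted subject points by the 6-parameter
// affine (par = s1, s2, sh1, sh2, o1, o2), bin on the reference frame,
// log-compress, Gaussian-smooth, and return the negative Pearson correlation
// with the (pre-smoothed, log-compressed, mass-matched) reference image.
// [[Rcpp::export]]
double cpp_reg_cost(const NumericVector& par, const NumericMatrix& pts,
                    const NumericVector& w,
                    double t1_lo, double t1_step,
                    double f_lo, double f_step, int bins,
                    const NumericVector& kernel,
                    const NumericMatrix& ref_smooth) {
  const double a11 = 1.0 + par[0], a22 = 1.0 + par[1];
  const double a12 = par[2], a21 = par[3];
  const double b1 = par[4], b2 = par[5];
  // degenerate transforms are rejected with a large cost
  if (std::fabs(a11 * a22 - a12 * a21) < 1e-6) return 1e6;

  NumericMatrix H(bins, bins);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    const double x = a11 * pts(i, 0) + a12 * pts(i, 1) + b1;
    const double y = a21 * pts(i, 0) + a22 * pts(i, 1) + b2;
    int ix = (int)std::floor((x - t1_lo) / t1_step);
    int iy = (int)std::floor((y - f_lo) / f_step);
    ix = std::min(std::max(ix, 0), bins - 1);
    iy = std::min(std::max(iy, 0), bins - 1);
    H(ix, iy) += w[i];
  }
  for (int i = 0; i < bins * bins; ++i) H[i] = std::log1p(H[i]);
  NumericMatrix Hs = cpp_smooth2d(H, kernel);

  const int N = bins * bins;
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < N; ++i) {
    const double x = Hs[i], y = ref_smooth[i];
    sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
  }
  const double vx = sxx - sx * sx / N, vy = syy - sy * sy / N;
  if (vx <= 0 || vy <= 0) return 1e6;
  const double r = (sxy - sx * sy / N) / std::sqrt(vx * vy);
  return -r;
}
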