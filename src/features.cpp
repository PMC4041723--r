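#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Images are H x W matrices indexed (row = y, col = x); exported coordinates
// are 0-based with x = column, y = row.

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Separable 2D convolution with edge-clamped padding. kx runs along x
// (columns), ky along y (rows). Kernels must have odd length.
// [[Rcpp::export]]
NumericMatrix cppConvSep(const NumericMatrix& img, const NumericVector& kx,
                         const NumericVector& ky) {
  const int H = img.nrow(), W = img.ncol();
  const int nx = kx.size(), ny = ky.size();
  const int cx = nx / 2, cy = ny / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // pass along x
  for (int x = 0; x < W; ++x) {
    for (int i = 0; i < nx; ++i) {
      const int xs = clampi(x + i - cx, W);
      const double w = kx[i];
      if (w == 0.0) continue;
      for (int y = 0; y < H; ++y) tmp(y, x) += w * img(y, xs);
    }
  }
  // pass along y
  for (int x = 0; x < W; ++x) {
    for (int i = 0; i < ny; ++i) {
      const int off = i - cy;
      const double w = ky[i];
      if (w == 0.0) continue;
      for (int y = 0; y < H; ++y) out(y, x) += w * tmp(clampi(y + off, H), x);
    }
  }
  return out;
}

// Scale-space maxima of a stack of response planes (list of H x W matrices,
// one per scale). A point is retained when its response exceeds `thresh` and
// is strictly greater than its 8 spatial neighbours in its own plane and all
// 9 neighbours in the planes directly above and below (interior scales only).
// Returns a matrix with columns: x, y, scaleIndex (1-based), strength.
// [[Rcpp::export]]
NumericMatrix cppScaleSpaceMaxima(const List& planes, double thresh) {
  const int S = planes.size();
  std::vector<NumericMatrix> R(S);
  for (int s = 0; s < S; ++s) R[s] = as<NumericMatrix>(planes[s]);
  const int H = R[0].nrow(), W = R[0].ncol();
  std::vector<double> rec;
  for (int s = 1; s + 1 < S; ++s) {
    const NumericMatrix &lo = R[s - 1], &cu = R[s], &hi = R[s + 1];
    for (int x = 1; x + 1 < W; ++x) {
      for (int y = 1; y + 1 < H; ++y) {
        const double v = cu(y, x);
        if (v <= thresh) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy) {
            if (!(dx == 0 && dy == 0) && cu(y + dy, x + dx) >= v) ismax = false;
            if (lo(y + dy, x + dx) >= v) ismax = false;
            if (hi(y + dy, x + dx) >= v) ismax = false;
          }
        if (ismax) {
          rec.push_back((double)x);
          rec.push_back((double)y);
          rec.push_back((double)(s + 1));
          rec.push_back(v);
        }
      }
    }
  }
  const int n = rec.size() / 4;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rec[4 * i + j];
  colnames(out) = CharacterVector::create("x", "y", "scaleIndex", "strength");
  return out;
}

// Bilinear resize to H2 x W2 (corner-aligned sampling).
// [[Rcpp::export]]
NumericMatrix cppResize(const NumericMatrix& img, int H2, int W2) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H2, W2);
  const double sy = (H2 > 1) ? (double)(H - 1) / (H2 - 1) : 0.0;
  const double sx = (W2 > 1) ? (double)(W - 1) / (W2 - 1) : 0.0;
  for (int x = 0; x < W2; ++x) {
    const double px = x * sx;
    const int x0 = (int)px, x1 = clampi(x0 + 1, W);
    const double fx = px - x0;
    for (int y = 0; y < H2; ++y) {
      const double py = y * sy;
      const int y0 = (int)py, y1 = clampi(y0 + 1, H);
      const double fy = py - y0;
      out(y, x) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

static inline double bilin(const NumericMatrix& img, double px, double py) {
  const int H = img.nrow(), W = img.ncol();
  if (px < 0) px = 0;
  if (py < 0) py = 0;
  if (px > W - 1) px = W - 1;
  if (py > H - 1) py = H - 1;
  const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
  const int x1 = clampi(x0 + 1, W), y1 = clampi(y0 + 1, H);
  const double fx = px - x0, fy = py - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// In-place max-accumulation of isotropic Gaussian alpha disks into A
// (used for vessel rendering in the synthetic generator).
// [[Rcpp::export]]
void cppMaxDisks(NumericMatrix A, const NumericVector& x,
                 const NumericVector& y, const NumericVector& s,
                 double amp) {
  const int H = A.nrow(), W = A.ncol();
  for (int p = 0; p < x.size(); ++p) {
    const double cx = x[p], cy = y[p], sg = s[p];
    const int ext = (int)std::ceil(3.0 * sg);
    const int x0 = std::max(0, (int)std::floor(cx) - ext);
    const int x1 = std::min(W - 1, (int)std::ceil(cx) + ext);
    const int y0 = std::max(0, (int)std::floor(cy) - ext);
    const int y1 = std::min(H - 1, (int)std::ceil(cy) + ext);
    const double inv = 1.0 / (2.0 * sg * sg);
    for (int xx = x0; xx <= x1; ++xx) {
      const double dx2 = (xx - cx) * (xx - cx);
      for (int yy = y0; yy <= y1; ++yy) {
        const double dy2 = (yy - cy) * (yy - cy);
        const double a = amp * std::exp(-(dx2 + dy2) * inv);
        if (a > A(yy, xx)) A(yy, xx) = a;
      }
    }
  }
}

// In-place alpha-blend of one (possibly rotated, elliptical) Gaussian blob
// into the three channel matrices.
// [[Rcpp::export]]
void cppStampBlob(NumericMatrix R, NumericMatrix G, NumericMatrix B,
                  double cx, double cy, double sx, double sy, double theta,
                  double amp, const NumericVector& color) {
  const int H = R.nrow(), W = R.ncol();
  const int ext = (int)std::ceil(3.0 * std::max(sx, sy));
  const int x0 = std::max(0, (int)std::floor(cx) - ext);
  const int x1 = std::min(W - 1, (int)std::ceil(cx) + ext);
  const int y0 = std::max(0, (int)std::floor(cy) - ext);
  const int y1 = std::min(H - 1, (int)std::ceil(cy) + ext);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double ix = 1.0 / (2.0 * sx * sx), iy = 1.0 / (2.0 * sy * sy);
  for (int xx = x0; xx <= x1; ++xx) {
    for (int yy = y0; yy <= y1; ++yy) {
      const double dx = xx - cx, dy = yy - cy;
      const double u = dx * ct + dy * st, v = -dx * st + dy * ct;
      const double a = amp * std::exp(-(u * u * ix + v * v * iy));
      R(yy, xx) = R(yy, xx) * (1 - a) + color[0] * a;
      G(yy, xx) = G(yy, xx) * (1 - a) + color[1] * a;
      B(yy, xx) = B(yy, xx) * (1 - a) + color[2] * a;
    }
  }
}

// Upright extended SURF-style descriptor: a 20x20 sample grid with step `s`
// centred on the keypoint, split into 4x4 subregions of 5x5 samples. Local
// gradients (central differences with step s, bilinear sampling, Gaussian
// weighted with sigma = 3.3 in grid units) are accumulated per subregion into
// the 8 extended bins: {sum dx, sum |dx|} split by sign(dy), and
// {sum dy, sum |dy|} split by sign(dx); 16 x 8 = 128 dimensions, then
// L2-normalised per descriptor. Sampling is edge-clamped.
// [[Rcpp::export]]
NumericMatrix cppSurfDescribe(const NumericMatrix& img, const NumericVector& x,
                              const NumericVector& y, const NumericVector& s) {
  const int n = x.size();
  NumericMatrix out(n, 128);
  const double sigw = 3.3;
  for (int i = 0; i < n; ++i) {
    const double step = s[i];
    for (int gi = -10; gi < 10; ++gi) {
      for (int gj = -10; gj < 10; ++gj) {
        const double u = gi + 0.5, v = gj + 0.5;
        const double px = x[i] + u * step, py = y[i] + v * step;
        const double w = std::exp(-(u * u + v * v) / (2.0 * sigw * sigw));
        const double dx =
            w * 0.5 * (bilin(img, px + step, py) - bilin(img, px - step, py));
        const double dy =
            w * 0.5 * (bilin(img, px, py + step) - bilin(img, px, py - step));
        const int si = (gi + 10) / 5, sj = (gj + 10) / 5;
        const int base = (si * 4 + sj) * 8;
        if (dy >= 0) {
          out(i, base + 0) += dx;
          out(i, base + 1) += std::fabs(dx);
        } else {
          out(i, base + 2) += dx;
          out(i, base + 3) += std::fabs(dx);
        }
        if (dx >= 0) {
          out(i, base + 4) += dy;
          out(i, base + 5) += std::fabs(dy);
        } else {
          out(i, base + 6) += dy;
          out(i, base + 7) += std::fabs(dy);
        }
      }
    }
    double nrm = 0.0;
    for (int k = 0; k < 128; ++k) nrm += out(i, k) * out(i, k);
    nrm = std::sqrt(nrm);
    if (nrm > 0) for (int k = 0; k < 128; ++k) out(i, k) /= nrm;
  }
  return out;
}
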