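#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate convention throughout: x rightward (column), y downward (row),
// 0-based pixel coordinates; image matrices are [row = y, col = x].
// Positive angles are anticlockwise as seen on screen, i.e. with y pointing
// down the rotation matrix is [cos, sin; -sin, cos].

static inline double bilinear(const NumericMatrix& img, double x, double y,
                              bool& oob) {
  const int h = img.nrow(), w = img.ncol();
  if (x < 0.0 || y < 0.0 || x > w - 1.0 || y > h - 1.0) {
    oob = true;
    return 0.0;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 == w - 1) x0--;
  if (y0 == h - 1) y0--;
  const double fx = x - x0, fy = y - y0;
  const double v00 = img(y0, x0),     v01 = img(y0, x0 + 1);
  const double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// [[Rcpp::export]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector x,
                                  NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    bool oob = false;
    double v = bilinear(img, x[i], y[i], oob);
    out[i] = oob ? NA_REAL : v;
  }
  return out;
}

// Normalized cross-correlation sweep of a point-sampled template over a grid
// of candidate rotations and a (2r+1)^2 lattice of candidate shifts.
//
// Template points (tx, ty) are integer-valued frame-0 pixel coordinates with
// values tv and 0/1 weights tw (metal-masked points get weight 0).  A
// candidate pose is: rotate the template by rot_deg[j] about its pivot
// (cx, cy), then translate by t_pred + R * (k, l).  Expressing the shift
// lattice in the rotated frame lets one resampling of the image per rotation
// serve every shift: sample S(u, v) = img at R*((u,v) - pivot) + pivot +
// t_pred over the template bounding box expanded by r, then shift (k, l)
// correlates tv[i] against S(tx[i] + k, ty[i] + l).
//
// Returns the NCC value for every (rotation, k, l) plus the out-of-bounds
// support fraction per rotation at the central shift.
// [[Rcpp::export]]
List ncc_sweep_cpp(NumericMatrix img, IntegerVector tx, IntegerVector ty,
                   NumericVector tv, NumericVector tw, double cx, double cy,
                   NumericVector rot_deg, double pred_dx, double pred_dy,
                   int radius) {
  const int n = tx.size(), nrot = rot_deg.size(), nsh = 2 * radius + 1;
  // template statistics (weighted)
  double sw = 0.0, st = 0.0, stt = 0.0;
  for (int i = 0; i < n; i++) {
    sw += tw[i];
    st += tw[i] * tv[i];
    stt += tw[i] * tv[i] * tv[i];
  }
  const double tmean = st / sw;
  const double tvar = stt / sw - tmean * tmean;

  int x0 = tx[0], x1 = tx[0], y0 = ty[0], y1 = ty[0];
  for (int i = 1; i < n; i++) {
    if (tx[i] < x0) x0 = tx[i];
    if (tx[i] > x1) x1 = tx[i];
    if (ty[i] < y0) y0 = ty[i];
    if (ty[i] > y1) y1 = ty[i];
  }
  const int bw = x1 - x0 + 1 + 2 * radius, bh = y1 - y0 + 1 + 2 * radius;
  std::vector<double> S((size_t)bw * bh);
  std::vector<char> So((size_t)bw * bh);

  NumericVector ncc(nrot * nsh * nsh);
  NumericVector oobfrac(nrot);

  // per-point base index into the resampled box (independent of rotation)
  std::vector<int> base(n);
  for (int i = 0; i < n; i++) {
    base[i] = (ty[i] - y0 + radius) * bw + (tx[i] - x0 + radius);
  }
  const bool unit_w = [&]() {
    for (int i = 0; i < n; i++) if (tw[i] != 1.0) return false;
    return true;
  }();
  const int nshift = nsh * nsh;
  std::vector<double> acc_si(nshift), acc_sii(nshift), acc_sti(nshift);

  for (int j = 0; j < nrot; j++) {
    const double th = rot_deg[j] * M_PI / 180.0;
    const double cth = std::cos(th), sth = std::sin(th);
    bool any_box_oob = false;
    for (int v = 0; v < bh; v++) {
      const double dy0 = (y0 - radius + v) - cy;
      for (int u = 0; u < bw; u++) {
        const double dx0 = (x0 - radius + u) - cx;
        const double sx = cx + pred_dx + cth * dx0 + sth * dy0;
        const double sy = cy + pred_dy - sth * dx0 + cth * dy0;
        bool oob = false;
        S[(size_t)v * bw + u] = bilinear(img, sx, sy, oob);
        So[(size_t)v * bw + u] = oob ? 1 : 0;
        any_box_oob |= oob;
      }
    }
    int n_oob_center = 0;
    if (any_box_oob) {
      for (int i = 0; i < n; i++) if (So[base[i]]) n_oob_center++;
    }
    oobfrac[j] = (double)n_oob_center / n;

    std::fill(acc_si.begin(), acc_si.end(), 0.0);
    std::fill(acc_sii.begin(), acc_sii.end(), 0.0);
    std::fill(acc_sti.begin(), acc_sti.end(), 0.0);
    // point-outer, shift-inner: the k loop reads contiguous memory and the
    // per-shift accumulators stay in cache/registers
    if (unit_w) {
      for (int i = 0; i < n; i++) {
        const double t = tv[i];
        const double* row0 = &S[base[i] - radius * bw - radius];
        int s = 0;
        for (int l = 0; l < nsh; l++) {
          const double* row = row0 + l * bw;
          for (int k = 0; k < nsh; k++, s++) {
            const double val = row[k];
            acc_si[s] += val;
            acc_sii[s] += val * val;
            acc_sti[s] += t * val;
          }
        }
      }
    } else {
      for (int i = 0; i < n; i++) {
        const double w = tw[i];
        if (w == 0.0) continue;
        const double t = tv[i];
        const double* row0 = &S[base[i] - radius * bw - radius];
        int s = 0;
        for (int l = 0; l < nsh; l++) {
          const double* row = row0 + l * bw;
          for (int k = 0; k < nsh; k++, s++) {
            const double val = row[k];
            acc_si[s] += w * val;
            acc_sii[s] += w * val * val;
            acc_sti[s] += w * t * val;
          }
        }
      }
    }
    for (int s = 0; s < nshift; s++) {
      const double imean = acc_si[s] / sw;
      const double ivar = acc_sii[s] / sw - imean * imean;
      double r;
      if (tvar <= 1e-12 || ivar <= 1e-12)
        r = 0.0;
      else
        r = (acc_sti[s] / sw - tmean * imean) / std::sqrt(tvar * ivar);
      if (any_box_oob) {
        // re-check this shift's support for off-field samples
        const int k = s % nsh - radius, l = s / nsh - radius;
        bool any_oob = false;
        for (int i = 0; i < n; i++) {
          if (tw[i] != 0.0 && So[base[i] + l * bw + k]) { any_oob = true; break; }
        }
        if (any_oob) r -= 2.0;  // never select poses sampling off the field
      }
      ncc[(size_t)j * nshift + s] = r;
    }
  }
  ncc.attr("dim") = IntegerVector::create(nsh, nsh, nrot);  // [k, l, rot]
  return List::create(_["ncc"] = ncc, _["oob_frac"] = oobfrac);
}

// Inverse-map homography warp: out(x, y) = img(hx / hz, hy / hz) with
// (hx, hy, hz)' = H (x, y, 1)', H the 3x3 inverse (output -> source) map.
// [[Rcpp::export]]
NumericMatrix warp_homography_cpp(NumericMatrix img, NumericMatrix H,
                                  double fill) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  for (int y = 0; y < h; y++) {
    for (int x = 0; x < w; x++) {
      const double hz = H(2, 0) * x + H(2, 1) * y + H(2, 2);
      const double sx = (H(0, 0) * x + H(0, 1) * y + H(0, 2)) / hz;
      const double sy = (H(1, 0) * x + H(1, 1) * y + H(1, 2)) / hz;
      bool oob = false;
      const double v = bilinear(img, sx, sy, oob);
      out(y, x) = oob ? fill : v;
    }
  }
  return out;
}

// Direct 2D convolution with a small kernel, replicate-padded borders.
// [[Rcpp::export]]
NumericMatrix convolve2d_cpp(NumericMatrix img, NumericMatrix kern) {
  const int h = img.nrow(), w = img.ncol();
  const int kh = kern.nrow(), kw = kern.ncol();
  const int oy = kh / 2, ox = kw / 2;
  NumericMatrix out(h, w);
  for (int y = 0; y < h; y++) {
    for (int x = 0; x < w; x++) {
      double acc = 0.0;
      for (int j = 0; j < kh; j++) {
        int yy = y + j - oy;
        if (yy < 0) yy = 0;
        if (yy >= h) yy = h - 1;
        for (int i = 0; i < kw; i++) {
          int xx = x + i - ox;
          if (xx < 0) xx = 0;
          if (xx >= w) xx = w - 1;
          acc += kern(j, i) * img(yy, xx);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Rasterize one vertebra: convex quadrilateral with rounded corners, bright
// cortical rim and graded interior, antialiased over 1 px.  Writes into img
// in place; returns false (drawing nothing) if the body plus margin leaves
// the field of view.  Corners are in canonical role order.
// [[Rcpp::export]]
bool draw_vertebra_cpp(NumericMatrix img, NumericMatrix corners,
                       double rho, double rim_width, double scale) {
  const int h = img.nrow(), w = img.ncol();
  const int margin = 4;
  double minx = corners(0, 0), maxx = minx, miny = corners(0, 1), maxy = miny;
  for (int i = 1; i < 4; i++) {
    minx = std::min(minx, corners(i, 0)); maxx = std::max(maxx, corners(i, 0));
    miny = std::min(miny, corners(i, 1)); maxy = std::max(maxy, corners(i, 1));
  }
  const int x0 = (int)std::floor(minx) - margin;
  const int x1 = (int)std::ceil(maxx) + margin;
  const int y0 = (int)std::floor(miny) - margin;
  const int y1 = (int)std::ceil(maxy) + margin;
  if (x0 < 0 || y0 < 0 || x1 > w - 1 || y1 > h - 1) return false;
  // inward edge normals and offsets
  double nx[4], ny[4], c0[4];
  double ctrx = 0, ctry = 0;
  for (int i = 0; i < 4; i++) { ctrx += corners(i, 0) / 4; ctry += corners(i, 1) / 4; }
  for (int e = 0; e < 4; e++) {
    const int f = (e + 1) % 4;
    double ex = corners(f, 0) - corners(e, 0), ey = corners(f, 1) - corners(e, 1);
    double len = std::sqrt(ex * ex + ey * ey);
    double nxx = -ey / len, nyy = ex / len;
    if ((ctrx - corners(e, 0)) * nxx + (ctry - corners(e, 1)) * nyy < 0) {
      nxx = -nxx; nyy = -nyy;
    }
    nx[e] = nxx; ny[e] = nyy;
    c0[e] = corners(e, 0) * nxx + corners(e, 1) * nyy;
  }
  const double rim_v = 220.0 * scale;
  // edges are feathered over +/- 1 px, emulating the imaging system's
  // point-spread blur (and giving sub-pixel edge estimators an unbiased,
  // symmetric intensity ramp)
  const double feather = 1.0;
  for (int y = y0; y <= y1; y++) {
    for (int x = x0; x <= x1; x++) {
      double s2 = 0.0;
      for (int e = 0; e < 4; e++) {
        const double de = x * nx[e] + y * ny[e] - c0[e];
        const double m = rho - de;
        if (m > 0) s2 += m * m;
      }
      const double g = rho - std::sqrt(s2);
      double alpha = (g + feather) / (2 * feather);
      if (alpha <= 0) continue;
      if (alpha > 1) alpha = 1;
      double wi = (g - rim_width + feather) / (2 * feather);
      if (wi < 0) wi = 0; else if (wi > 1) wi = 1;
      double iv = (150.0 - 0.25 * (g - rim_width));
      if (iv < 110.0) iv = 110.0;
      const double val = rim_v * (1 - wi) + iv * scale * wi;
      const double bg = img(y, x);
      img(y, x) = bg + alpha * (val - bg);
    }
  }
  return true;
}
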