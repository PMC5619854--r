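// Count-conserving polar regridding primitives.
//
// The detector image is resampled onto a (radius x azimuth) grid by clipping
// each pixel's transformed quadrilateral against the grid cells with the
// Sutherland-Hodgman algorithm and redistributing counts by fractional
// overlap area, so the total number of counts is conserved in both
// directions.  The wrapped azimuthal median filter and the Jacobi diffusion
// fill used to clean and complete the polar image live here too: they run on
// every model build and are the hot loops of the pipeline.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double TWO_PI = 2.0 * M_PI;

// signed shoelace area; positive for counter-clockwise vertex order
static double shoelace(const std::vector<double>& x, const std::vector<double>& y) {
  double a = 0.0;
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

// Clip polygon (xs, ys) by the half-plane on the left of directed edge
// (ex0,ey0)->(ex1,ey1).  Standard Sutherland-Hodgman stage.
static void clip_edge(std::vector<double>& xs, std::vector<double>& ys,
                      double ex0, double ey0, double ex1, double ey1) {
  const size_t n = xs.size();
  if (n == 0) return;
  std::vector<double> ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  const double dx = ex1 - ex0, dy = ey1 - ey0;
  for (size_t i = 0; i < n; ++i) {
    const size_t j = (i + 1) % n;
    const double cx = xs[i], cy = ys[i], nx = xs[j], ny = ys[j];
    const double sc = dx * (cy - ey0) - dy * (cx - ex0);  // >=0: inside
    const double sn = dx * (ny - ey0) - dy * (nx - ex0);
    if (sc >= 0) {
      ox.push_back(cx);
      oy.push_back(cy);
    }
    if ((sc > 0 && sn < 0) || (sc < 0 && sn > 0)) {
      const double t = sc / (sc - sn);
      ox.push_back(cx + t * (nx - cx));
      oy.push_back(cy + t * (ny - cy));
    }
  }
  xs.swap(ox);
  ys.swap(oy);
}

// clip convex polygon against axis-aligned rectangle, return |area|
static double clip_rect_area(const std::vector<double>& px,
                             const std::vector<double>& py,
                             double x0, double x1, double y0, double y1) {
  std::vector<double> xs(px), ys(py);
  clip_edge(xs, ys, x0, y0, x1, y0);  // bottom, inside above
  clip_edge(xs, ys, x1, y0, x1, y1);  // right
  clip_edge(xs, ys, x1, y1, x0, y1);  // top
  clip_edge(xs, ys, x0, y1, x0, y0);  // left
  if (xs.size() < 3) return 0.0;
  return std::fabs(shoelace(xs, ys));
}

// [[Rcpp::export]]
NumericMatrix cpp_clip_polygon(NumericMatrix subject, NumericMatrix clip) {
  std::vector<double> xs, ys;
  for (int i = 0; i < subject.nrow(); ++i) {
    xs.push_back(subject(i, 0));
    ys.push_back(subject(i, 1));
  }
  // ensure clip polygon is counter-clockwise
  std::vector<double> cx, cy;
  for (int i = 0; i < clip.nrow(); ++i) {
    cx.push_back(clip(i, 0));
    cy.push_back(clip(i, 1));
  }
  if (shoelace(cx, cy) < 0) {
    std::reverse(cx.begin(), cx.end());
    std::reverse(cy.begin(), cy.end());
  }
  const size_t m = cx.size();
  for (size_t e = 0; e < m && !xs.empty(); ++e) {
    size_t f = (e + 1) % m;
    clip_edge(xs, ys, cx[e], cy[e], cx[f], cy[f]);
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix poly) {
  std::vector<double> xs, ys;
  for (int i = 0; i < poly.nrow(); ++i) {
    xs.push_back(poly(i, 0));
    ys.push_back(poly(i, 1));
  }
  if (xs.size() < 3) return 0.0;
  return std::fabs(shoelace(xs, ys));
}

// Overlap fractions between detector pixels and polar-grid cells.
//
// Pixel (i, j), 0-based, occupies [i, i+1) x [j, j+1) in slow/fast units.
// Its four corners are mapped to (azimuth, radius) about the beam centre;
// the straight-edged quadrilateral of the transformed corners is clipped
// against every candidate cell rectangle.  Quadrilaterals spanning the
// +/- pi azimuth seam are handled by unwrapping the negative corners by
// 2*pi and clipping against periodic copies of the cell rectangles.
// Pixels any corner of which lies within min_radius of the beam centre are
// excluded (radial interpolation degenerates there).
//
// Returns 1-based linear indices: pixel index into an (n_slow x n_fast)
// matrix, cell index into an (n_res x n_az) matrix.
// [[Rcpp::export]]
List cpp_overlap_fractions(int n_slow, int n_fast,
                           double bc_slow, double bc_fast,
                           NumericVector res_edges,
                           int n_az, double az0,
                           double min_radius) {
  const int n_res = res_edges.size() - 1;
  const double daz = TWO_PI / n_az;
  std::vector<int> out_pix, out_cell;
  std::vector<double> out_frac;
  out_pix.reserve(4 * (size_t)n_slow * n_fast);
  out_cell.reserve(4 * (size_t)n_slow * n_fast);
  out_frac.reserve(4 * (size_t)n_slow * n_fast);

  std::vector<double> qx(4), qy(4);
  for (int j = 0; j < n_fast; ++j) {
    for (int i = 0; i < n_slow; ++i) {
      // corners in order around the pixel square
      const double cs[4] = {(double)i, (double)i + 1, (double)i + 1, (double)i};
      const double cf[4] = {(double)j, (double)j, (double)j + 1, (double)j + 1};
      double rmin = R_PosInf, rmax = 0.0;
      bool bad = false;
      for (int k = 0; k < 4; ++k) {
        const double ds = cs[k] - bc_slow, df = cf[k] - bc_fast;
        const double r = std::hypot(ds, df);
        if (r < min_radius) { bad = true; break; }
        qx[k] = std::atan2(df, ds);   // azimuth in (-pi, pi]
        qy[k] = r;
        rmin = std::min(rmin, r);
        rmax = std::max(rmax, r);
      }
      if (bad) continue;
      // seam: if azimuth span exceeds pi the quad crosses +/- pi
      double amin = *std::min_element(qx.begin(), qx.end());
      double amax = *std::max_element(qx.begin(), qx.end());
      if (amax - amin > M_PI) {
        for (int k = 0; k < 4; ++k) if (qx[k] < 0) qx[k] += TWO_PI;
        amin = *std::min_element(qx.begin(), qx.end());
        amax = *std::max_element(qx.begin(), qx.end());
      }
      // quad must be counter-clockwise for the clipper
      std::vector<double> px(qx), py(qy);
      double qa = shoelace(px, py);
      if (qa < 0) {
        std::reverse(px.begin(), px.end());
        std::reverse(py.begin(), py.end());
        qa = -qa;
      }
      if (qa <= 0) continue;  // degenerate

      // candidate radial bins
      const double* re = res_edges.begin();
      int rb0 = (int)(std::upper_bound(re, re + n_res + 1, rmin) - re) - 1;
      int rb1 = (int)(std::upper_bound(re, re + n_res + 1, rmax) - re) - 1;
      rb0 = std::max(rb0, 0);
      rb1 = std::min(rb1, n_res - 1);
      // candidate azimuth bins in continuous index space (periodic copies)
      const int k0 = (int)std::floor((amin - az0) / daz);
      const int k1 = (int)std::floor((amax - az0) / daz);

      const int pix = i + j * n_slow + 1;
      for (int rb = rb0; rb <= rb1; ++rb) {
        for (int k = k0; k <= k1; ++k) {
          const double a = clip_rect_area(px, py,
                                          az0 + k * daz, az0 + (k + 1) * daz,
                                          re[rb], re[rb + 1]);
          if (a <= 0) continue;
          int ab = k % n_az;
          if (ab < 0) ab += n_az;
          out_pix.push_back(pix);
          out_cell.push_back(rb + ab * n_res + 1);
          out_frac.push_back(a / qa);
        }
      }
    }
  }
  return List::create(_["pixel"] = wrap(out_pix),
                      _["cell"] = wrap(out_cell),
                      _["frac"] = wrap(out_frac));
}

// counts -> polar: values[cell] += frac * img[pixel], weight[cell] += frac,
// over unmasked pixels only
// [[Rcpp::export]]
List cpp_accumulate_polar(IntegerVector pixel, IntegerVector cell,
                          NumericVector frac, NumericVector img,
                          LogicalVector mask, int ncell) {
  NumericVector values(ncell), weight(ncell);
  const int n = pixel.size();
  for (int t = 0; t < n; ++t) {
    const int p = pixel[t] - 1;
    if (!mask[p]) continue;
    const int c = cell[t] - 1;
    values[c] += frac[t] * img[p];
    weight[c] += frac[t];
  }
  return List::create(_["values"] = values, _["weight"] = weight);
}

// polar -> detector: out[pixel] += frac * cellvals[cell]; wsum tracks the
// total fraction recovered per pixel (1 for on-grid pixels)
// [[Rcpp::export]]
List cpp_scatter_detector(IntegerVector pixel, IntegerVector cell,
                          NumericVector frac, NumericVector cellvals,
                          int npix) {
  NumericVector out(npix), wsum(npix);
  const int n = pixel.size();
  for (int t = 0; t < n; ++t) {
    const int p = pixel[t] - 1;
    out[p] += frac[t] * cellvals[cell[t] - 1];
    wsum[p] += frac[t];
  }
  return List::create(_["values"] = out, _["wsum"] = wsum);
}

// Median filter along the azimuth (wrapped) direction of the polar image.
// Each valid cell is replaced by the median over itself and its nnbr
// nearest valid neighbours along the same radial row; invalid cells are
// skipped entirely.  Rows with fewer than nnbr + 1 valid cells are left
// unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter_az(NumericMatrix vals, LogicalMatrix valid,
                                   int nnbr) {
  const int n_res = vals.nrow(), n_az = vals.ncol();
  NumericMatrix out = clone(vals);
  const int lo = nnbr / 2, hi = nnbr - lo;  // window size nnbr + 1
  std::vector<int> idx;
  std::vector<double> v, w;
  idx.reserve(n_az);
  v.reserve(n_az);
  w.resize(nnbr + 1);
  for (int r = 0; r < n_res; ++r) {
    idx.clear();
    v.clear();
    for (int a = 0; a < n_az; ++a) {
      if (valid(r, a)) {
        idx.push_back(a);
        v.push_back(vals(r, a));
      }
    }
    const int m = (int)idx.size();
    if (m < nnbr + 1) continue;
    for (int t = 0; t < m; ++t) {
      for (int o = -lo; o <= hi; ++o) {
        int s = (t + o) % m;
        if (s < 0) s += m;
        w[o + lo] = v[s];
      }
      std::vector<double> ww(w);
      const int half = (int)ww.size() / 2;
      std::nth_element(ww.begin(), ww.begin() + half, ww.end());
      double med = ww[half];
      if (ww.size() % 2 == 0) {
        std::nth_element(ww.begin(), ww.begin() + half - 1, ww.begin() + half);
        med = 0.5 * (med + ww[half - 1]);
      }
      out(r, idx[t]) = med;
    }
  }
  return out;
}

// Jacobi iteration for Laplace's equation over invalid cells with the valid
// cells as Dirichlet data.  Azimuth (columns) wraps; radius (rows) does not.
// The domain restricts the fill to cells that overlap the detector at all:
// cells wholly outside it keep their initial value and do not participate
// as neighbours.  tol is an absolute threshold on the largest
// per-iteration update.  Invalid entries of vals must already hold their
// initial guess.
// [[Rcpp::export]]
List cpp_diffusion_fill(NumericMatrix vals, LogicalMatrix valid,
                        LogicalMatrix domain, double tol, int max_iter) {
  const int n_res = vals.nrow(), n_az = vals.ncol();
  NumericMatrix cur = clone(vals);
  std::vector<int> ur, ua;  // unknown cells
  for (int a = 0; a < n_az; ++a)
    for (int r = 0; r < n_res; ++r)
      if (domain(r, a) && !valid(r, a)) {
        ur.push_back(r);
        ua.push_back(a);
      }
  const size_t nu = ur.size();
  bool converged = (nu == 0);
  int it = 0;
  if (nu > 0) {
    std::vector<double> upd(nu);
    for (it = 1; it <= max_iter; ++it) {
      double dmax = 0.0;
      for (size_t u = 0; u < nu; ++u) {
        const int r = ur[u], a = ua[u];
        const int al = (a == 0) ? n_az - 1 : a - 1;
        const int ah = (a == n_az - 1) ? 0 : a + 1;
        double s = 0.0;
        int nn = 0;
        if (domain(r, al)) { s += cur(r, al); ++nn; }
        if (domain(r, ah)) { s += cur(r, ah); ++nn; }
        if (r > 0 && domain(r - 1, a)) { s += cur(r - 1, a); ++nn; }
        if (r < n_res - 1 && domain(r + 1, a)) { s += cur(r + 1, a); ++nn; }
        upd[u] = (nn > 0) ? s / nn : cur(r, a);
        const double d = std::fabs(upd[u] - cur(r, a));
        if (d > dmax) dmax = d;
      }
      for (size_t u = 0; u < nu; ++u) cur(ur[u], ua[u]) = upd[u];
      if (dmax < tol) { converged = true; break; }
    }
    if (it > max_iter) it = max_iter;
  }
  return List::create(_["values"] = cur, _["n_iter"] = it,
                      _["converged"] = converged);
}
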