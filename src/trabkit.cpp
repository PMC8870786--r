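#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact 1D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2004). f holds per-site offsets (0 at sites,
// +inf elsewhere); d receives min_j (i-j)^2 + f[j].
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // no sites at all
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared EDT of a binary site matrix (TRUE = site / distance 0),
// distances in grid units. Used on the 2x-refined grid by the aperture map.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& site) {
  const int H = site.nrow(), W = site.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // pass 1: along columns (rows vary)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = site(i, j) ? 0.0 : INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) D(i, j) = d[i];
  }
  // pass 2: along rows
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = D(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) D(i, j) = d[j];
  }
  return D;
}

// ---------------------------------------------------------------------------
// Aperture map: per foreground pixel, the diameter (in pixel units) of the
// largest disk fully contained in the phase (phase = union of closed unit
// pixel squares; outside the image counts as background) that covers the
// pixel centre. Disk centres live on the half-integer fine grid; the radius
// at a centre is its exact Euclidean distance to the background region,
// obtained from a point-EDT on the fine grid (the nearest point of an
// axis-aligned background square to any fine sample is itself a fine sample).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_aperture_px(const LogicalMatrix& fg) {
  const int H = fg.nrow(), W = fg.ncol();
  const int FH = 2 * H - 1, FW = 2 * W - 1; // fine grid, spacing 1/2 px
  // distance is measured to in-image background squares only: the image
  // border does not truncate disks (a region-of-interest cut must not bias
  // the thickness map), so a mask with no background has unbounded disks,
  // capped at the image diagonal.
  const double rcap = 0.5 * std::sqrt((double)H * H + (double)W * W);
  // fine sample (a,b) sits at pixel coords (a/2, b/2); it belongs to the
  // background region iff any pixel whose closed unit square contains it is
  // background
  LogicalMatrix bgfine(FH, FW);
  for (int a = 0; a < FH; ++a) {
    int i0 = a / 2, i1 = (a + 1) / 2; // containing pixel rows (equal if a even)
    for (int b = 0; b < FW; ++b) {
      int j0 = b / 2, j1 = (b + 1) / 2;
      bool bg = !fg(i0, j0) || !fg(i0, j1) || !fg(i1, j0) || !fg(i1, j1);
      bgfine(a, b) = bg;
    }
  }
  NumericMatrix dsq = cpp_edt_sq(bgfine); // squared distance in fine units
  NumericMatrix out(H, W);
  const double eps = 1e-9;
  // radius at fine sample, in coarse pixel units
  std::vector<double> r(FH * (size_t)FW);
  for (int a = 0; a < FH; ++a)
    for (int b = 0; b < FW; ++b) {
      double v = 0.5 * std::sqrt(dsq(a, b));
      r[a + (size_t)FH * b] = (v > rcap || !std::isfinite(v)) ? rcap : v;
    }
  const double sq2 = std::sqrt(2.0);
  for (int a = 0; a < FH; ++a) {
    for (int b = 0; b < FW; ++b) {
      double rc = r[a + (size_t)FH * b];
      if (rc <= 0.0) continue;
      // prune centres whose disk is contained in a fine-neighbour's disk
      bool contained = false;
      for (int da = -1; da <= 1 && !contained; ++da) {
        for (int db = -1; db <= 1; ++db) {
          if (da == 0 && db == 0) continue;
          int aa = a + da, bb = b + db;
          if (aa < 0 || aa >= FH || bb < 0 || bb >= FW) continue;
          double dn = (da != 0 && db != 0) ? 0.5 * sq2 : 0.5;
          if (r[aa + (size_t)FH * bb] >= rc + dn - eps &&
              r[aa + (size_t)FH * bb] > rc + eps) {
            contained = true;
            break;
          }
        }
      }
      if (contained) continue;
      double cy = 0.5 * a, cx = 0.5 * b; // centre in pixel coords (0-based)
      double diam = 2.0 * rc;
      int ilo = (int)std::ceil(cy - rc - eps), ihi = (int)std::floor(cy + rc + eps);
      if (ilo < 0) ilo = 0;
      if (ihi > H - 1) ihi = H - 1;
      for (int i = ilo; i <= ihi; ++i) {
        double dy = i - cy;
        double w2 = rc * rc - dy * dy;
        if (w2 < -eps) continue;
        double wxd = std::sqrt(std::max(w2, 0.0));
        int jlo = (int)std::ceil(cx - wxd - eps), jhi = (int)std::floor(cx + wxd + eps);
        if (jlo < 0) jlo = 0;
        if (jhi > W - 1) jhi = W - 1;
        for (int j = jlo; j <= jhi; ++j) {
          if (!fg(i, j)) continue;
          if (diam > out(i, j)) out(i, j) = diam;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable convolution with reflect (mirror) padding. k is centred (odd
// length). Applied along rows (dim = 1 convolves down columns, i.e. the row
// index) or columns (dim = 2).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_conv1(const NumericMatrix& x, const NumericVector& k, int dim) {
  const int H = x.nrow(), W = x.ncol(), n = k.size(), h = n / 2;
  NumericMatrix out(H, W);
  auto refl = [](int i, int N) {
    while (i < 0 || i >= N) {
      if (i < 0) i = -i - 1;
      if (i >= N) i = 2 * N - 1 - i;
    }
    return i;
  };
  if (dim == 1) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += k[t] * x(refl(i + t - h, H), j);
        out(i, j) = s;
      }
  } else {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += k[t] * x(i, refl(j + t - h, W));
        out(i, j) = s;
      }
  }
  return out;
}

// 4-connected component labelling of a logical matrix; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int t = 0; t < 4; ++t) {
          int ni = ci + di[t], nj = cj + dj[t];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (m(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  return lab;
}
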