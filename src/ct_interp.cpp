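// Scattered-data C1 cubic interpolation: reduced Clough-Tocher (HCT) element
// evaluated on a caller-supplied Delaunay triangulation.
//
// Each macro triangle is split at its centroid into three cubic Bezier
// mini-patches. Corner values and gradients fix the boundary ordinates; the
// interior ordinates follow from (i) requiring the cross-edge normal
// derivative to vary linearly along each outer edge (the "reduced" condition,
// which gives quadratic precision when exact gradients are supplied) and
// (ii) C1 continuity across the three internal edges, which yields the
// closed forms
//   q_i = (c_i + m_left + m_right) / 3,    z = (q1 + q2 + q3) / 3.
// Vertex gradients are estimated by distance-weighted least squares over
// Delaunay neighbours (exact for linear fields).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Distance-weighted least-squares gradient at each data site, using the
// one-ring Delaunay neighbourhood. tri is 1-based, ntri x 3.
// [[Rcpp::export]]
NumericMatrix cp_estimate_gradients(const NumericVector& x,
                                    const NumericVector& y,
                                    const NumericVector& f,
                                    const IntegerMatrix& tri) {
  const int n = x.size(), nt = tri.nrow();
  std::vector<std::vector<int> > nbr(n);
  for (int t = 0; t < nt; ++t) {
    int v[3] = {tri(t, 0) - 1, tri(t, 1) - 1, tri(t, 2) - 1};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        if (a != b) nbr[v[a]].push_back(v[b]);
  }
  NumericMatrix g(n, 2);
  for (int i = 0; i < n; ++i) {
    std::vector<int>& nb = nbr[i];
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    double sxx = 0, sxy = 0, syy = 0, bx = 0, by = 0;
    for (size_t k = 0; k < nb.size(); ++k) {
      double dx = x[nb[k]] - x[i], dy = y[nb[k]] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 <= 0) continue;
      double w = 1.0 / d2, df = f[nb[k]] - f[i];
      sxx += w * dx * dx; sxy += w * dx * dy; syy += w * dy * dy;
      bx += w * dx * df;  by += w * dy * df;
    }
    double ridge = 1e-12 * (sxx + syy);
    sxx += ridge; syy += ridge;
    double det = sxx * syy - sxy * sxy;
    if (det > 0) {
      g(i, 0) = (syy * bx - sxy * by) / det;
      g(i, 1) = (sxx * by - sxy * bx) / det;
    } // else leave zero (isolated / degenerate neighbourhood)
  }
  return g;
}

struct EdgeKey {
  int a, b;
  bool operator==(const EdgeKey& o) const { return a == o.a && b == o.b; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& e) const {
    return std::hash<long long>()((long long)e.a * 1000003LL + e.b);
  }
};

// Ordinate slots per macro triangle (see mapping in eval below)
enum { F1, F2, F3, E12, E21, E23, E32, E31, E13, C1o, C2o, C3o,
       M12, M23, M31, Q1, Q2, Q3, ZC, NORD };

static void ct_ordinates(const double* xs, const double* ys,
                         const double* fs, const double* gx,
                         const double* gy, double* o) {
  const double cx = (xs[0] + xs[1] + xs[2]) / 3.0;
  const double cy = (ys[0] + ys[1] + ys[2]) / 3.0;
  o[F1] = fs[0]; o[F2] = fs[1]; o[F3] = fs[2];
  // edge and centre-directed ordinates from corner gradients
  o[E12] = fs[0] + (gx[0] * (xs[1] - xs[0]) + gy[0] * (ys[1] - ys[0])) / 3.0;
  o[E21] = fs[1] + (gx[1] * (xs[0] - xs[1]) + gy[1] * (ys[0] - ys[1])) / 3.0;
  o[E23] = fs[1] + (gx[1] * (xs[2] - xs[1]) + gy[1] * (ys[2] - ys[1])) / 3.0;
  o[E32] = fs[2] + (gx[2] * (xs[1] - xs[2]) + gy[2] * (ys[1] - ys[2])) / 3.0;
  o[E31] = fs[2] + (gx[2] * (xs[0] - xs[2]) + gy[2] * (ys[0] - ys[2])) / 3.0;
  o[E13] = fs[0] + (gx[0] * (xs[2] - xs[0]) + gy[0] * (ys[2] - ys[0])) / 3.0;
  o[C1o] = fs[0] + (gx[0] * (cx - xs[0]) + gy[0] * (cy - ys[0])) / 3.0;
  o[C2o] = fs[1] + (gx[1] * (cx - xs[1]) + gy[1] * (cy - ys[1])) / 3.0;
  o[C3o] = fs[2] + (gx[2] * (cx - xs[2]) + gy[2] * (cy - ys[2])) / 3.0;
  // interior ordinate m of each mini-patch from the linear normal-derivative
  // condition on its outer edge
  const int ia[3] = {0, 1, 2}, ib[3] = {1, 2, 0};
  const double b300[3] = {o[F1], o[F2], o[F3]};
  const double b030[3] = {o[F2], o[F3], o[F1]};
  const double b210[3] = {o[E12], o[E23], o[E31]};
  const double b120[3] = {o[E21], o[E32], o[E13]};
  const double b201[3] = {o[C1o], o[C2o], o[C3o]};
  const double b021[3] = {o[C2o], o[C3o], o[C1o]};
  for (int k = 0; k < 3; ++k) {
    const double ax = xs[ia[k]], ay = ys[ia[k]];
    const double bx2 = xs[ib[k]], by2 = ys[ib[k]];
    const double nx = -(by2 - ay), ny = bx2 - ax; // edge normal (unnormalised)
    // barycentric direction coords (a,b,c) of n w.r.t. (A, B, centre)
    const double m11 = bx2 - ax, m12v = cx - ax;
    const double m21 = by2 - ay, m22 = cy - ay;
    const double det = m11 * m22 - m12v * m21;
    const double bb = (nx * m22 - m12v * ny) / det;
    const double cc = (m11 * ny - nx * m21) / det;
    const double aa = -bb - cc;
    o[M12 + k] = ((aa * (b300[k] + b120[k]) + bb * (b210[k] + b030[k]) +
                   cc * (b201[k] + b021[k])) / 2.0 -
                  aa * b210[k] - bb * b120[k]) / cc;
  }
  // C1 across internal edges
  o[Q1] = (o[C1o] + o[M31] + o[M12]) / 3.0;
  o[Q2] = (o[C2o] + o[M12] + o[M23]) / 3.0;
  o[Q3] = (o[C3o] + o[M23] + o[M31]) / 3.0;
  o[ZC] = (o[Q1] + o[Q2] + o[Q3]) / 3.0;
}

// Evaluate the CT interpolant at query points. Returns NA for points outside
// the convex hull of the data. tri is 1-based; point location walks the
// triangulation via shared-edge adjacency built here.
// [[Rcpp::export]]
NumericVector cp_ct_eval(const NumericVector& x, const NumericVector& y,
                         const NumericVector& f, const NumericMatrix& grad,
                         const IntegerMatrix& tri,
                         const NumericVector& qx, const NumericVector& qy) {
  const int nt = tri.nrow(), nq = qx.size();
  // adjacency: neighbour of triangle t across the edge opposite local vertex k
  std::unordered_map<EdgeKey, std::pair<int, int>, EdgeHash> emap;
  emap.reserve(nt * 2);
  std::vector<int> nbr(nt * 3, -1);
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < 3; ++k) {
      int a = tri(t, (k + 1) % 3), b = tri(t, (k + 2) % 3);
      EdgeKey e = {std::min(a, b), std::max(a, b)};
      std::unordered_map<EdgeKey, std::pair<int, int>, EdgeHash>::iterator it = emap.find(e);
      if (it == emap.end()) emap[e] = std::make_pair(t, k);
      else {
        nbr[t * 3 + k] = it->second.first;
        nbr[it->second.first * 3 + it->second.second] = t;
      }
    }
  }
  std::vector<double> ords(nt * NORD);
  std::vector<char> have(nt, 0);
  NumericVector out(nq);
  const double tol = 1e-9;
  int cur = 0;
  for (int q = 0; q < nq; ++q) {
    double px = qx[q], py = qy[q];
    int t = cur, found = -1, steps = 0;
    double l1 = 0, l2 = 0, l3 = 0;
    while (t >= 0 && steps++ <= 4 * nt) {
      const int v1 = tri(t, 0) - 1, v2 = tri(t, 1) - 1, v3 = tri(t, 2) - 1;
      const double x1 = x[v1], y1 = y[v1];
      const double det = (x[v2] - x1) * (y[v3] - y1) - (x[v3] - x1) * (y[v2] - y1);
      if (det == 0) { t = -2; break; } // degenerate: fall through to scan
      l2 = ((px - x1) * (y[v3] - y1) - (py - y1) * (x[v3] - x1)) / det;
      l3 = ((py - y1) * (x[v2] - x1) - (px - x1) * (y[v2] - y1)) / det;
      l1 = 1.0 - l2 - l3;
      int worst = (l1 <= l2 && l1 <= l3) ? 0 : ((l2 <= l3) ? 1 : 2);
      double wl = (worst == 0) ? l1 : (worst == 1 ? l2 : l3);
      if (wl >= -tol) { found = t; break; }
      t = nbr[t * 3 + worst];
    }
    if (found < 0 && t == -2) {
      // rare degenerate walk: brute-force scan
      for (int s = 0; s < nt && found < 0; ++s) {
        const int v1 = tri(s, 0) - 1, v2 = tri(s, 1) - 1, v3 = tri(s, 2) - 1;
        const double x1 = x[v1], y1 = y[v1];
        const double det = (x[v2] - x1) * (y[v3] - y1) - (x[v3] - x1) * (y[v2] - y1);
        if (det == 0) continue;
        l2 = ((px - x1) * (y[v3] - y1) - (py - y1) * (x[v3] - x1)) / det;
        l3 = ((py - y1) * (x[v2] - x1) - (px - x1) * (y[v2] - y1)) / det;
        l1 = 1.0 - l2 - l3;
        if (l1 >= -tol && l2 >= -tol && l3 >= -tol) found = s;
      }
    }
    if (found < 0) { out[q] = NA_REAL; continue; }
    cur = found;
    if (!have[found]) {
      double xs[3], ys[3], fs[3], gxv[3], gyv[3];
      for (int k = 0; k < 3; ++k) {
        int v = tri(found, k) - 1;
        xs[k] = x[v]; ys[k] = y[v]; fs[k] = f[v];
        gxv[k] = grad(v, 0); gyv[k] = grad(v, 1);
      }
      ct_ordinates(xs, ys, fs, gxv, gyv, &ords[found * NORD]);
      have[found] = 1;
    }
    const double* o = &ords[found * NORD];
    // mini-patch = the one excluding the vertex with smallest barycentric
    int k = (l1 <= l2 && l1 <= l3) ? 0 : ((l2 <= l3) ? 1 : 2);
    double lam[3] = {l1, l2, l3};
    int i = (k + 1) % 3, j = (k + 2) % 3;
    double u = lam[i] - lam[k], v = lam[j] - lam[k], w = 3.0 * lam[k];
    // Bezier ordinates of mini (V_i, V_j, centre); minis are stored in the
    // order (V1,V2,C), (V2,V3,C), (V3,V1,C) indexed by i
    double b300 = o[F1 + i], b030 = o[F1 + j], b003 = o[ZC];
    double b210 = o[E12 + 2 * i], b120 = o[E12 + 2 * i + 1];
    double b201 = o[C1o + i], b021 = o[C1o + j];
    double b102 = o[Q1 + i], b012 = o[Q1 + j];
    double b111 = o[M12 + i];
    out[q] = b300 * u * u * u + b030 * v * v * v + b003 * w * w * w +
             3.0 * (b210 * u * u * v + b201 * u * u * w + b120 * u * v * v +
                    b021 * v * v * w + b102 * u * w * w + b012 * v * w * w) +
             6.0 * b111 * u * v * w;
  }
  return out;
}
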