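#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Incremental (Bowyer-Watson) Delaunay triangulation.
//
// Coordinates are normalised to ~[0,1] before insertion; a large enclosing
// super-triangle guarantees every insertion point falls inside an existing
// triangle. Triangles are stored CCW; tn[3*t+k] is the neighbour across the
// edge opposite vertex k (-1 at the boundary). Near-cocircular points are
// resolved deterministically by insertion order (strict in-circle test).

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d strictly inside circumcircle of CCW triangle abc
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

struct Triangulator {
  std::vector<double> px, py;       // point coords (normalised)
  std::vector<int> tv;              // 3 vertex ids per triangle
  std::vector<int> tn;              // 3 neighbour ids per triangle
  std::vector<char> dead;
  int last_tri = 0;

  int nt() const { return (int)tv.size() / 3; }

  int add_tri(int a, int b, int c) {
    tv.push_back(a); tv.push_back(b); tv.push_back(c);
    tn.push_back(-1); tn.push_back(-1); tn.push_back(-1);
    dead.push_back(0);
    return nt() - 1;
  }

  // index of vertex a within triangle t
  int vidx(int t, int a) const {
    for (int k = 0; k < 3; ++k) if (tv[3 * t + k] == a) return k;
    return -1;
  }

  // walk from last_tri to the triangle containing (x, y)
  int locate(double x, double y) {
    int t = last_tri;
    int guard = 4 * nt() + 64;
    while (guard-- > 0) {
      if (dead[t]) { // restart from any live triangle
        t = -1;
        for (int i = nt() - 1; i >= 0; --i) if (!dead[i]) { t = i; break; }
        if (t < 0) Rcpp::stop("triangulation exhausted");
      }
      int a = tv[3 * t], b = tv[3 * t + 1], c = tv[3 * t + 2];
      double o0 = orient2d(px[b], py[b], px[c], py[c], x, y); // edge opp a
      double o1 = orient2d(px[c], py[c], px[a], py[a], x, y); // edge opp b
      double o2 = orient2d(px[a], py[a], px[b], py[b], x, y); // edge opp c
      int k = -1;
      double worst = -1e-14;
      if (o0 < worst) { worst = o0; k = 0; }
      if (o1 < worst) { worst = o1; k = 1; }
      if (o2 < worst) { worst = o2; k = 2; }
      if (k < 0) { last_tri = t; return t; }
      int nb = tn[3 * t + k];
      if (nb < 0) { last_tri = t; return t; } // on hull (shouldn't happen)
      t = nb;
    }
    // fallback: linear scan
    for (int i = 0; i < nt(); ++i) {
      if (dead[i]) continue;
      int a = tv[3 * i], b = tv[3 * i + 1], c = tv[3 * i + 2];
      if (orient2d(px[b], py[b], px[c], py[c], x, y) >= -1e-12 &&
          orient2d(px[c], py[c], px[a], py[a], x, y) >= -1e-12 &&
          orient2d(px[a], py[a], px[b], py[b], x, y) >= -1e-12) {
        last_tri = i; return i;
      }
    }
    Rcpp::stop("point location failed");
  }

  void insert(int ip) {
    double x = px[ip], y = py[ip];
    int t0 = locate(x, y);

    // grow the cavity of triangles whose circumcircle contains p
    std::vector<int> bad, stack;
    std::unordered_map<int, char> inbad;
    stack.push_back(t0); inbad[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      for (int k = 0; k < 3; ++k) {
        int nb = tn[3 * t + k];
        if (nb < 0 || inbad.count(nb)) continue;
        int a = tv[3 * nb], b = tv[3 * nb + 1], c = tv[3 * nb + 2];
        if (incircle(px[a], py[a], px[b], py[b], px[c], py[c], x, y) > 1e-14) {
          inbad[nb] = 1; stack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity, in triangle-CCW orientation
    struct Edge { int a, b, outer; };
    std::vector<Edge> edges;
    for (int t : bad) {
      for (int k = 0; k < 3; ++k) {
        int nb = tn[3 * t + k];
        if (nb >= 0 && inbad.count(nb)) continue;
        Edge e;
        e.a = tv[3 * t + (k + 1) % 3];
        e.b = tv[3 * t + (k + 2) % 3];
        e.outer = nb;
        edges.push_back(e);
      }
    }
    for (int t : bad) dead[t] = 1;

    // fan of new triangles (p, a, b); link them to each other and outward
    std::unordered_map<int, int> byA, byB; // edge first/second vertex -> new tri
    std::vector<int> newt(edges.size());
    for (size_t i = 0; i < edges.size(); ++i) {
      int t = add_tri(ip, edges[i].a, edges[i].b);
      newt[i] = t;
      tn[3 * t + 0] = edges[i].outer;
      if (edges[i].outer >= 0) {
        int nb = edges[i].outer;
        for (int k = 0; k < 3; ++k) {
          if (tv[3 * nb + (k + 1) % 3] == edges[i].b &&
              tv[3 * nb + (k + 2) % 3] == edges[i].a) {
            tn[3 * nb + k] = t; break;
          }
        }
      }
      byA[edges[i].a] = t;
      byB[edges[i].b] = t;
    }
    for (size_t i = 0; i < edges.size(); ++i) {
      int t = newt[i];
      // edge opposite vertex 1 (=a) is (b, p): neighbour has a' == b
      tn[3 * t + 1] = byA.count(edges[i].b) ? byA[edges[i].b] : -1;
      // edge opposite vertex 2 (=b) is (p, a): neighbour has b' == a
      tn[3 * t + 2] = byB.count(edges[i].a) ? byB[edges[i].a] : -1;
    }
    if (!newt.empty()) last_tri = newt[0];
  }
};

// interleave 16-bit coordinates into a Morton key for spatially coherent
// insertion order (keeps the locate() walk short)
static inline uint64_t morton_key(uint32_t ix, uint32_t iy) {
  uint64_t key = 0;
  for (int b = 0; b < 16; ++b) {
    key |= (uint64_t)((ix >> b) & 1u) << (2 * b);
    key |= (uint64_t)((iy >> b) & 1u) << (2 * b + 1);
  }
  return key;
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("points are coincident or collinear");

  Triangulator T;
  T.px.resize(n + 3); T.py.resize(n + 3);
  for (int i = 0; i < n; ++i) {
    T.px[i] = (x[i] - xmin) / span;
    T.py[i] = (y[i] - ymin) / span;
  }
  // super-triangle far outside the unit box; must clear the circumcircle
  // of any thin hull sliver or that sliver is lost with the super vertices
  T.px[n] = -1e6;  T.py[n] = -1e6;
  T.px[n + 1] = 3e6; T.py[n + 1] = -1e6;
  T.px[n + 2] = -1e6; T.py[n + 2] = 3e6;
  T.add_tri(n, n + 1, n + 2);

  // deterministic spatial (Morton) insertion order; the point index is
  // folded into the sort key so ties are broken reproducibly
  std::vector<uint64_t> keys(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    uint32_t ix = (uint32_t)(T.px[i] * 65535.0);
    uint32_t iy = (uint32_t)(T.py[i] * 65535.0);
    keys[i] = (morton_key(ix, iy) << 21) | (uint64_t)i;
    ord[i] = i;
  }
  std::sort(ord.begin(), ord.end(),
            [&keys](int a, int b) { return keys[a] < keys[b]; });
  for (int i = 0; i < n; ++i) T.insert(ord[i]);

  int m = 0;
  for (int t = 0; t < T.nt(); ++t) {
    if (T.dead[t]) continue;
    if (T.tv[3 * t] >= n || T.tv[3 * t + 1] >= n || T.tv[3 * t + 2] >= n)
      continue;
    ++m;
  }
  IntegerMatrix tri(m, 3);
  int r = 0;
  for (int t = 0; t < T.nt(); ++t) {
    if (T.dead[t]) continue;
    int a = T.tv[3 * t], b = T.tv[3 * t + 1], c = T.tv[3 * t + 2];
    if (a >= n || b >= n || c >= n) continue;
    tri(r, 0) = a + 1; tri(r, 1) = b + 1; tri(r, 2) = c + 1;
    ++r;
  }
  return tri;
}

// Assign every pixel of a regular grid to its enclosing triangle and record
// the barycentric weights. Grid pixel (iy, ix) has centre
// (x0 + ix*dx, y0 + iy*dy) and linear index iy + ix*ny (R column-major with
// rows = y). tri_id is 1-based, 0 = outside the triangulation.
// [[Rcpp::export]]
List cpp_grid_bary(NumericVector x, NumericVector y, IntegerMatrix tri,
                   double x0, double dx, int nx,
                   double y0, double dy, int ny, double tol) {
  int npix = nx * ny;
  IntegerVector tid(npix, 0);
  IntegerMatrix verts(npix, 3);
  NumericMatrix w(npix, 3);
  int m = tri.nrow();
  for (int t = 0; t < m; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    double x1 = x[a], y1 = y[a], x2 = x[b], y2 = y[b], x3 = x[c], y3 = y[c];
    double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (std::fabs(det) < 1e-300) continue;
    double txmin = std::min(x1, std::min(x2, x3));
    double txmax = std::max(x1, std::max(x2, x3));
    double tymin = std::min(y1, std::min(y2, y3));
    double tymax = std::max(y1, std::max(y2, y3));
    int i0 = (int)std::ceil((txmin - x0) / dx - 1e-9);
    int i1 = (int)std::floor((txmax - x0) / dx + 1e-9);
    int j0 = (int)std::ceil((tymin - y0) / dy - 1e-9);
    int j1 = (int)std::floor((tymax - y0) / dy + 1e-9);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 >= nx) i1 = nx - 1;
    if (j1 >= ny) j1 = ny - 1;
    for (int ix = i0; ix <= i1; ++ix) {
      double qx = x0 + ix * dx;
      for (int iy = j0; iy <= j1; ++iy) {
        int l = iy + ix * ny;
        if (tid[l] != 0) continue;
        double qy = y0 + iy * dy;
        double l2 = ((qx - x1) * (y3 - y1) - (x3 - x1) * (qy - y1)) / det;
        if (l2 < -tol || l2 > 1 + tol) continue;
        double l3 = ((x2 - x1) * (qy - y1) - (qx - x1) * (y2 - y1)) / det;
        if (l3 < -tol) continue;
        double l1 = 1.0 - l2 - l3;
        if (l1 < -tol) continue;
        tid[l] = t + 1;
        verts(l, 0) = a + 1; verts(l, 1) = b + 1; verts(l, 2) = c + 1;
        w(l, 0) = l1; w(l, 1) = l2; w(l, 2) = l3;
      }
    }
  }
  return List::create(_["tri_id"] = tid, _["verts"] = verts, _["bary"] = w);
}

// Paint Gaussian spots of unit peak height scaled by val onto an ny x nx
// image (R column-major, rows = y). Positions are 0-based pixel coords.
// [[Rcpp::export]]
NumericMatrix cpp_render_spots(NumericVector x, NumericVector y,
                               NumericVector val, double sigma,
                               int nx, int ny) {
  NumericMatrix img(ny, nx);
  int n = x.size();
  int halo = (int)std::ceil(4.0 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(x[i]);
    int cy = (int)std::floor(y[i]);
    for (int ix = cx - halo; ix <= cx + halo + 1; ++ix) {
      if (ix < 0 || ix >= nx) continue;
      double ddx = ix - x[i];
      for (int iy = cy - halo; iy <= cy + halo + 1; ++iy) {
        if (iy < 0 || iy >= ny) continue;
        double ddy = iy - y[i];
        img(iy, ix) += val[i] * std::exp(-(ddx * ddx + ddy * ddy) * inv2s2);
      }
    }
  }
  return img;
}

// Normalized cross-correlation of a template against every placement inside
// a search image. Returns the (S-T+1) x (S-T+1) correlation surface; the
// entry at (r, c) (0-based) places the template top-left at search (r, c).
// [[Rcpp::export]]
NumericMatrix cpp_ncc(NumericMatrix search, NumericMatrix templ) {
  int sr = search.nrow(), sc = search.ncol();
  int tr = templ.nrow(), tc = templ.ncol();
  if (tr > sr || tc > sc) stop("template larger than search region");
  int orows = sr - tr + 1, ocols = sc - tc + 1;
  double n = (double)tr * tc;
  double tsum = 0, tsum2 = 0;
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) { tsum += templ(i, j); tsum2 += templ(i, j) * templ(i, j); }
  double tvar = tsum2 - tsum * tsum / n;
  if (tvar <= 0) stop("template has zero variance");
  NumericMatrix out(orows, ocols);
  for (int oc = 0; oc < ocols; ++oc) {
    for (int orow = 0; orow < orows; ++orow) {
      double ssum = 0, ssum2 = 0, cross = 0;
      for (int j = 0; j < tc; ++j) {
        for (int i = 0; i < tr; ++i) {
          double v = search(orow + i, oc + j);
          ssum += v; ssum2 += v * v;
          cross += v * templ(i, j);
        }
      }
      double svar = ssum2 - ssum * ssum / n;
      double denom = std::sqrt(svar * tvar);
      out(orow, oc) = denom > 1e-300 ? (cross - ssum * tsum / n) / denom : 0.0;
    }
  }
  return out;
}
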