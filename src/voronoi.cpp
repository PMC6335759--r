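#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voronoi-adjacency by direct half-plane clipping.
//
// For each generator point the Voronoi cell is constructed by clipping an
// initial convex polygon (the ROI bounding box) against the perpendicular
// bisector half-plane of every other generator, nearest first, with an early
// exit once the remaining generators are provably too far to cut the current
// polygon (d/2 exceeds the polygon's circumradius about the generator).
// Each polygon edge carries the index of the bisector that created it, so
// the Voronoi neighbors and the shared boundary segments fall out directly.

struct ClipPoly {
  std::vector<double> x, y; // vertex k starts edge k -> k+1 (cyclic)
  std::vector<int> src;     // bisector index owning edge k, -1 = boundary
};

// Clip convex polygon against half-plane a.(p) <= b, new edge labelled j.
static void clip_halfplane(ClipPoly &p, double ax, double ay, double b, int j) {
  size_t m = p.x.size();
  if (m == 0) return;
  std::vector<double> d(m);
  bool any_out = false, any_in = false;
  for (size_t k = 0; k < m; ++k) {
    d[k] = ax * p.x[k] + ay * p.y[k] - b;
    if (d[k] > 0) any_out = true; else any_in = true;
  }
  if (!any_out) return;              // fully inside, nothing to do
  if (!any_in) { p.x.clear(); p.y.clear(); p.src.clear(); return; }
  ClipPoly q;
  q.x.reserve(m + 2); q.y.reserve(m + 2); q.src.reserve(m + 2);
  for (size_t k = 0; k < m; ++k) {
    size_t k1 = (k + 1) % m;
    double d0 = d[k], d1 = d[k1];
    if (d0 <= 0) {
      q.x.push_back(p.x[k]); q.y.push_back(p.y[k]); q.src.push_back(p.src[k]);
      if (d1 > 0) { // exiting: intersection starts the new bisector edge
        double t = d0 / (d0 - d1);
        q.x.push_back(p.x[k] + t * (p.x[k1] - p.x[k]));
        q.y.push_back(p.y[k] + t * (p.y[k1] - p.y[k]));
        q.src.push_back(j);
      }
    } else if (d1 <= 0) { // entering: remainder of edge k survives
      double t = d0 / (d0 - d1);
      q.x.push_back(p.x[k] + t * (p.x[k1] - p.x[k]));
      q.y.push_back(p.y[k] + t * (p.y[k1] - p.y[k]));
      q.src.push_back(p.src[k]);
    }
  }
  p = q;
}

// [[Rcpp::export]]
List voronoi_adjacency_cpp(NumericVector x, NumericVector y,
                           NumericVector clip_x, NumericVector clip_y,
                           double eps) {
  int n = x.size();
  int m0 = clip_x.size();
  std::vector<int> ord(n);
  std::vector<int> out_i, out_j;
  std::vector<double> ox1, oy1, ox2, oy2;

  for (int i = 0; i < n; ++i) {
    ClipPoly poly;
    poly.x.assign(clip_x.begin(), clip_x.end());
    poly.y.assign(clip_y.begin(), clip_y.end());
    poly.src.assign(m0, -1);

    // other points sorted by squared distance to i
    std::vector<std::pair<double,int> > dist;
    dist.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      dist.push_back(std::make_pair(dx * dx + dy * dy, j));
    }
    std::sort(dist.begin(), dist.end());

    double maxr2 = 0;
    for (size_t k = 0; k < poly.x.size(); ++k) {
      double dx = poly.x[k] - x[i], dy = poly.y[k] - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 > maxr2) maxr2 = r2;
    }

    for (size_t q = 0; q < dist.size(); ++q) {
      if (0.25 * dist[q].first > maxr2) break; // bisector cannot reach polygon
      int j = dist[q].second;
      double ax = x[j] - x[i], ay = y[j] - y[i];
      double b = ax * 0.5 * (x[i] + x[j]) + ay * 0.5 * (y[i] + y[j]);
      clip_halfplane(poly, ax, ay, b, j);
      if (poly.x.empty()) break; // generator outside clip region
      maxr2 = 0;
      for (size_t k = 0; k < poly.x.size(); ++k) {
        double dx = poly.x[k] - x[i], dy = poly.y[k] - y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 > maxr2) maxr2 = r2;
      }
    }

    size_t m = poly.x.size();
    for (size_t k = 0; k < m; ++k) {
      if (poly.src[k] < 0) continue;
      size_t k1 = (k + 1) % m;
      double dx = poly.x[k1] - poly.x[k], dy = poly.y[k1] - poly.y[k];
      if (std::sqrt(dx * dx + dy * dy) <= eps) continue;
      out_i.push_back(i + 1);
      out_j.push_back(poly.src[k] + 1);
      ox1.push_back(poly.x[k]);  oy1.push_back(poly.y[k]);
      ox2.push_back(poly.x[k1]); oy2.push_back(poly.y[k1]);
    }
  }

  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x1"] = wrap(ox1), _["y1"] = wrap(oy1),
                      _["x2"] = wrap(ox2), _["y2"] = wrap(oy2));
}
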