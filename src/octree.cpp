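// Octree spatial index over 3-D points with inclusive radius and
// nearest-neighbour queries. Points are stored once; nodes keep index
// ranges after an in-place partition, so memory stays O(n).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <memory>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct OctNode {
  double cx, cy, cz, half;          // cubic cell: centre + half side
  int lo, hi;                        // index range into the point order
  bool leaf;
  std::array<std::unique_ptr<OctNode>, 8> child;
  OctNode(double x, double y, double z, double h, int l, int u)
      : cx(x), cy(y), cz(z), half(h), lo(l), hi(u), leaf(true) {}
};

class Octree {
 public:
  std::vector<double> px, py, pz;    // original coordinates
  std::vector<int> order;            // permutation: node ranges index this
  std::unique_ptr<OctNode> root;
  int leaf_capacity;

  Octree(const NumericMatrix& pts, int cap) : leaf_capacity(cap) {
    int n = pts.nrow();
    px.resize(n); py.resize(n); pz.resize(n);
    order.resize(n);
    double mn[3], mx[3];
    for (int d = 0; d < 3; ++d) {
      mn[d] = std::numeric_limits<double>::infinity();
      mx[d] = -mn[d];
    }
    for (int i = 0; i < n; ++i) {
      px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
      order[i] = i;
      if (!R_finite(px[i]) || !R_finite(py[i]) || !R_finite(pz[i]))
        stop("octree points must be finite");
      mn[0] = std::min(mn[0], px[i]); mx[0] = std::max(mx[0], px[i]);
      mn[1] = std::min(mn[1], py[i]); mx[1] = std::max(mx[1], py[i]);
      mn[2] = std::min(mn[2], pz[i]); mx[2] = std::max(mx[2], pz[i]);
    }
    if (n == 0) { root.reset(); return; }
    double half = 0.0;
    for (int d = 0; d < 3; ++d) half = std::max(half, (mx[d] - mn[d]) / 2.0);
    half = half * 1.0000001 + 1e-12;   // strictly contain all points
    root.reset(new OctNode((mn[0] + mx[0]) / 2.0, (mn[1] + mx[1]) / 2.0,
                           (mn[2] + mx[2]) / 2.0, half, 0, n));
    split(root.get(), 0);
  }

  void split(OctNode* nd, int depth) {
    if (nd->hi - nd->lo <= leaf_capacity || depth >= 24) return;
    nd->leaf = false;
    // bucket points into octants
    std::array<std::vector<int>, 8> buf;
    for (int k = nd->lo; k < nd->hi; ++k) {
      int i = order[k];
      int oct = (px[i] >= nd->cx) | ((py[i] >= nd->cy) << 1) |
                ((pz[i] >= nd->cz) << 2);
      buf[oct].push_back(i);
    }
    int pos = nd->lo;
    double q = nd->half / 2.0;
    for (int oc = 0; oc < 8; ++oc) {
      if (buf[oc].empty()) continue;
      int start = pos;
      for (int i : buf[oc]) order[pos++] = i;
      double ox = nd->cx + ((oc & 1) ? q : -q);
      double oy = nd->cy + ((oc & 2) ? q : -q);
      double oz = nd->cz + ((oc & 4) ? q : -q);
      nd->child[oc].reset(new OctNode(ox, oy, oz, q, start, pos));
      split(nd->child[oc].get(), depth + 1);
    }
  }

  // minimum squared distance from point to a node's cube
  static double box_dist2(const OctNode* nd, double x, double y, double z) {
    double dx = std::max(std::fabs(x - nd->cx) - nd->half, 0.0);
    double dy = std::max(std::fabs(y - nd->cy) - nd->half, 0.0);
    double dz = std::max(std::fabs(z - nd->cz) - nd->half, 0.0);
    return dx * dx + dy * dy + dz * dz;
  }

  void query(const OctNode* nd, double x, double y, double z, double r2,
             std::vector<int>& out) const {
    if (!nd || box_dist2(nd, x, y, z) > r2) return;
    if (nd->leaf) {
      for (int k = nd->lo; k < nd->hi; ++k) {
        int i = order[k];
        double dx = px[i] - x, dy = py[i] - y, dz = pz[i] - z;
        if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(i);
      }
      return;
    }
    for (const auto& c : nd->child) query(c.get(), x, y, z, r2, out);
  }

  void nearest(const OctNode* nd, double x, double y, double z,
               double& best2, int& best) const {
    if (!nd || box_dist2(nd, x, y, z) >= best2) return;
    if (nd->leaf) {
      for (int k = nd->lo; k < nd->hi; ++k) {
        int i = order[k];
        double dx = px[i] - x, dy = py[i] - y, dz = pz[i] - z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best2) { best2 = d2; best = i; }
      }
      return;
    }
    // visit children closest-first
    std::array<std::pair<double, const OctNode*>, 8> ord;
    int m = 0;
    for (const auto& c : nd->child)
      if (c) ord[m++] = {box_dist2(c.get(), x, y, z), c.get()};
    std::sort(ord.begin(), ord.begin() + m);
    for (int j = 0; j < m; ++j) nearest(ord[j].second, x, y, z, best2, best);
  }
};

// [[Rcpp::export(name = ".octree_build")]]
SEXP octree_build_cpp(NumericMatrix pts, int leaf_capacity) {
  if (leaf_capacity < 1) stop("leaf_capacity must be >= 1");
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  XPtr<Octree> p(new Octree(pts, leaf_capacity), true);
  return p;
}

// [[Rcpp::export(name = ".octree_size")]]
int octree_size_cpp(SEXP tree) {
  XPtr<Octree> p(tree);
  return (int)p->px.size();
}

// [[Rcpp::export(name = ".octree_query")]]
IntegerVector octree_query_cpp(SEXP tree, NumericVector center, double r) {
  if (r < 0) stop("query radius must be non-negative");
  XPtr<Octree> p(tree);
  std::vector<int> out;
  if (p->root)
    p->query(p->root.get(), center[0], center[1], center[2], r * r, out);
  std::sort(out.begin(), out.end());
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;  // 1-based
  return res;
}

// Batched radius query: returns a list of 1-based index vectors.
// [[Rcpp::export(name = ".octree_query_many")]]
List octree_query_many_cpp(SEXP tree, NumericMatrix centers, double r) {
  if (r < 0) stop("query radius must be non-negative");
  XPtr<Octree> p(tree);
  int m = centers.nrow();
  List res(m);
  std::vector<int> out;
  for (int j = 0; j < m; ++j) {
    out.clear();
    if (p->root)
      p->query(p->root.get(), centers(j, 0), centers(j, 1), centers(j, 2),
               r * r, out);
    std::sort(out.begin(), out.end());
    IntegerVector v(out.size());
    for (size_t i = 0; i < out.size(); ++i) v[i] = out[i] + 1;
    res[j] = v;
  }
  return res;
}

// Batched nearest neighbour: id (1-based, NA if empty) and distance.
// [[Rcpp::export(name = ".octree_nearest_many")]]
List octree_nearest_many_cpp(SEXP tree, NumericMatrix centers) {
  XPtr<Octree> p(tree);
  int m = centers.nrow();
  IntegerVector ids(m);
  NumericVector dist(m);
  for (int j = 0; j < m; ++j) {
    double best2 = std::numeric_limits<double>::infinity();
    int best = -1;
    if (p->root)
      p->nearest(p->root.get(), centers(j, 0), centers(j, 1), centers(j, 2),
                 best2, best);
    if (best < 0) {
      ids[j] = NA_INTEGER;
      dist[j] = NA_REAL;
    } else {
      ids[j] = best + 1;
      dist[j] = std::sqrt(best2);
    }
  }
  return List::create(_["id"] = ids, _["dist"] = dist);
}
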