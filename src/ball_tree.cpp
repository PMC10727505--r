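#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// Exact ball tree (metric tree) over points in R^d with Euclidean metric.
// Supports k-nearest-neighbor and radius queries.  Both are exact: pruning
// uses the triangle-inequality lower bound max(0, d(q, center) - radius).
// Ties in distance are broken by ascending point index so that results are
// deterministic and match a brute-force scan sorted by (distance, index).

namespace {

struct Node {
  int start, end;     // range into the permutation array `order`
  int left, right;    // child node ids, -1 for leaf
  double radius;      // max distance from center to any point in range
  std::vector<double> center;
};

struct BallTree {
  int n, d, leaf_size;
  std::vector<double> pts;  // n x d, row-major
  std::vector<int> order;   // permutation of 0..n-1
  std::vector<Node> nodes;

  const double* point(int i) const { return &pts[(size_t)i * d]; }

  double dist(const double* a, const double* b) const {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double diff = a[k] - b[k];
      s += diff * diff;
    }
    return std::sqrt(s);
  }

  int build(int start, int end) {
    Node nd;
    nd.start = start;
    nd.end = end;
    nd.left = nd.right = -1;
    nd.center.assign(d, 0.0);
    for (int i = start; i < end; ++i) {
      const double* p = point(order[i]);
      for (int k = 0; k < d; ++k) nd.center[k] += p[k];
    }
    const double inv = 1.0 / (end - start);
    for (int k = 0; k < d; ++k) nd.center[k] *= inv;
    nd.radius = 0.0;
    for (int i = start; i < end; ++i) {
      double dd = dist(nd.center.data(), point(order[i]));
      if (dd > nd.radius) nd.radius = dd;
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (end - start > leaf_size) {
      // split along the dimension of maximum spread at the median
      int dim = 0;
      double best_spread = -1.0;
      for (int k = 0; k < d; ++k) {
        double lo = point(order[start])[k], hi = lo;
        for (int i = start + 1; i < end; ++i) {
          double v = point(order[i])[k];
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (hi - lo > best_spread) {
          best_spread = hi - lo;
          dim = k;
        }
      }
      int mid = start + (end - start) / 2;
      const std::vector<double>& P = pts;
      int D = d;
      std::nth_element(order.begin() + start, order.begin() + mid,
                       order.begin() + end, [&P, D, dim](int a, int b) {
                         double va = P[(size_t)a * D + dim];
                         double vb = P[(size_t)b * D + dim];
                         if (va != vb) return va < vb;
                         return a < b;
                       });
      int left = build(start, mid);
      int right = build(mid, end);
      nodes[id].left = left;
      nodes[id].right = right;
    }
    return id;
  }
};

struct Neighbor {
  double dist;
  int index;
};

// Comparator for a max-heap whose top is the WORST retained neighbor
// under the (distance, index) lexicographic order.
struct NeighborBetter {
  bool operator()(const Neighbor& a, const Neighbor& b) const {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.index < b.index;
  }
};

typedef std::priority_queue<Neighbor, std::vector<Neighbor>, NeighborBetter>
    NeighborHeap;

bool beats(const Neighbor& cand, const Neighbor& worst) {
  if (cand.dist != worst.dist) return cand.dist < worst.dist;
  return cand.index < worst.index;
}

void knn_recurse(const BallTree& tree, int node_id, const double* q, int k,
                 NeighborHeap& heap) {
  const Node& nd = tree.nodes[node_id];
  double dc = tree.dist(q, nd.center.data());
  double lower = dc - nd.radius;
  if (lower < 0.0) lower = 0.0;
  if ((int)heap.size() == k && lower > heap.top().dist) return;
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.end; ++i) {
      int pi = tree.order[i];
      Neighbor cand{tree.dist(q, tree.point(pi)), pi};
      if ((int)heap.size() < k) {
        heap.push(cand);
      } else if (beats(cand, heap.top())) {
        heap.pop();
        heap.push(cand);
      }
    }
    return;
  }
  double dl = tree.dist(q, tree.nodes[nd.left].center.data());
  double dr = tree.dist(q, tree.nodes[nd.right].center.data());
  if (dl <= dr) {
    knn_recurse(tree, nd.left, q, k, heap);
    knn_recurse(tree, nd.right, q, k, heap);
  } else {
    knn_recurse(tree, nd.right, q, k, heap);
    knn_recurse(tree, nd.left, q, k, heap);
  }
}

void radius_recurse(const BallTree& tree, int node_id, const double* q,
                    double r, std::vector<Neighbor>& out) {
  const Node& nd = tree.nodes[node_id];
  double dc = tree.dist(q, nd.center.data());
  if (dc - nd.radius > r) return;
  if (dc + nd.radius <= r) {
    // whole ball inside the query radius
    for (int i = nd.start; i < nd.end; ++i) {
      int pi = tree.order[i];
      out.push_back(Neighbor{tree.dist(q, tree.point(pi)), pi});
    }
    return;
  }
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.end; ++i) {
      int pi = tree.order[i];
      double dd = tree.dist(q, tree.point(pi));
      if (dd <= r) out.push_back(Neighbor{dd, pi});
    }
    return;
  }
  radius_recurse(tree, nd.left, q, r, out);
  radius_recurse(tree, nd.right, q, r, out);
}

}  // namespace

// [[Rcpp::export]]
SEXP bt_build(NumericMatrix pts, int leaf_size = 40) {
  if (pts.nrow() < 1) stop("ball tree requires at least one point");
  if (leaf_size < 1) stop("leaf_size must be positive");
  XPtr<BallTree> tree(new BallTree(), true);
  tree->n = pts.nrow();
  tree->d = pts.ncol();
  tree->leaf_size = leaf_size;
  tree->pts.resize((size_t)tree->n * tree->d);
  for (int i = 0; i < tree->n; ++i)
    for (int k = 0; k < tree->d; ++k)
      tree->pts[(size_t)i * tree->d + k] = pts(i, k);
  tree->order.resize(tree->n);
  for (int i = 0; i < tree->n; ++i) tree->order[i] = i;
  tree->nodes.reserve(2 * tree->n / leaf_size + 4);
  tree->build(0, tree->n);
  return tree;
}

// [[Rcpp::export]]
int bt_size(SEXP tree_ptr) {
  XPtr<BallTree> tree(tree_ptr);
  return tree->n;
}

// Returns 1-based indices and distances of the k nearest points per query
// row, ordered by ascending (distance, index).
// [[Rcpp::export]]
List bt_knn(SEXP tree_ptr, NumericMatrix queries, int k) {
  XPtr<BallTree> tree(tree_ptr);
  if (queries.ncol() != tree->d)
    stop("query dimensionality does not match the index");
  if (k < 1 || k > tree->n)
    stop("k must be between 1 and the number of indexed points");
  int nq = queries.nrow();
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<double> qbuf(tree->d);
  for (int qi = 0; qi < nq; ++qi) {
    for (int kk = 0; kk < tree->d; ++kk) qbuf[kk] = queries(qi, kk);
    NeighborHeap heap;
    knn_recurse(*tree, 0, qbuf.data(), k, heap);
    std::vector<Neighbor> res(heap.size());
    for (int pos = (int)heap.size() - 1; pos >= 0; --pos) {
      res[pos] = heap.top();
      heap.pop();
    }
    for (int pos = 0; pos < k; ++pos) {
      idx(qi, pos) = res[pos].index + 1;
      dist(qi, pos) = res[pos].dist;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Returns, per query row, all points within (inclusive) radius r, ordered
// by ascending (distance, index).  Flat encoding: `lengths[q]` results per
// query, concatenated in `idx`/`dist`.
// [[Rcpp::export]]
List bt_radius(SEXP tree_ptr, NumericMatrix queries, double r) {
  XPtr<BallTree> tree(tree_ptr);
  if (queries.ncol() != tree->d)
    stop("query dimensionality does not match the index");
  if (r < 0) stop("radius must be non-negative");
  int nq = queries.nrow();
  std::vector<int> all_idx;
  std::vector<double> all_dist;
  IntegerVector lengths(nq);
  std::vector<double> qbuf(tree->d);
  std::vector<Neighbor> res;
  for (int qi = 0; qi < nq; ++qi) {
    for (int kk = 0; kk < tree->d; ++kk) qbuf[kk] = queries(qi, kk);
    res.clear();
    radius_recurse(*tree, 0, qbuf.data(), r, res);
    std::sort(res.begin(), res.end(), [](const Neighbor& a, const Neighbor& b) {
      if (a.dist != b.dist) return a.dist < b.dist;
      return a.index < b.index;
    });
    lengths[qi] = (int)res.size();
    for (size_t i = 0; i < res.size(); ++i) {
      all_idx.push_back(res[i].index + 1);
      all_dist.push_back(res[i].dist);
    }
  }
  return List::create(_["lengths"] = lengths,
                      _["idx"] = IntegerVector(all_idx.begin(), all_idx.end()),
                      _["dist"] = NumericVector(all_dist.begin(), all_dist.end()));
}
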