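#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Exact 3-d k-d tree nearest-neighbour search.
//
// Elastic registration and ICP both rely on *exact* nearest neighbours:
// an approximate match can stall convergence or break the monotone-RMS
// property, so no approximation is used. Ties in distance are broken by
// the lowest reference index, which keeps every downstream result
// deterministic across platforms.

namespace {

struct KDNode {
  int point;      // index into the reference array
  int axis;       // split axis 0/1/2
  int left;       // child node ids, -1 if leaf
  int right;
};

class KDTree {
public:
  KDTree(const double* pts, int n) : pts_(pts), n_(n) {
    idx_.resize(n);
    for (int i = 0; i < n; ++i) idx_[i] = i;
    nodes_.reserve(2 * n);
    root_ = build(0, n, 0);
  }

  void nearest(const double* q, int& best_idx, double& best_d2) const {
    best_idx = -1;
    best_d2 = R_PosInf;
    search(root_, q, best_idx, best_d2);
  }

private:
  const double* pts_;
  int n_;
  std::vector<int> idx_;
  std::vector<KDNode> nodes_;
  int root_;

  double coord(int i, int ax) const { return pts_[i + ax * n_]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = lo + (hi - lo) / 2;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    KDNode nd;
    nd.point = idx_[mid];
    nd.axis = ax;
    int id = (int)nodes_.size();
    nodes_.push_back(nd);
    // children assigned after recursion; vector may reallocate, so index by id
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  void search(int node, const double* q, int& best_idx, double& best_d2) const {
    if (node < 0) return;
    const KDNode& nd = nodes_[node];
    int p = nd.point;
    double dx = q[0] - coord(p, 0);
    double dy = q[1] - coord(p, 1);
    double dz = q[2] - coord(p, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best_d2 || (d2 == best_d2 && p < best_idx)) {
      best_d2 = d2;
      best_idx = p;
    }
    double diff = q[nd.axis] - coord(p, nd.axis);
    int first = (diff < 0) ? nd.left : nd.right;
    int second = (diff < 0) ? nd.right : nd.left;
    search(first, q, best_idx, best_d2);
    // explore the far side whenever it could hold an equal-or-closer point:
    // equality must be explored so the lowest-index tie wins
    if (diff * diff <= best_d2) search(second, q, best_idx, best_d2);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_nearest")]]
Rcpp::List cpp_nearest(Rcpp::NumericMatrix query, Rcpp::NumericMatrix ref) {
  if (ref.nrow() == 0) Rcpp::stop("reference point set is empty");
  if (query.ncol() != 3 || ref.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  int nq = query.nrow();
  KDTree tree(REAL(ref), ref.nrow());
  Rcpp::IntegerVector idx(nq);
  Rcpp::NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    int bi;
    double bd2;
    tree.nearest(q, bi, bd2);
    idx[i] = bi + 1;  // 1-based for R
    dist[i] = std::sqrt(bd2);
  }
  return Rcpp::List::create(Rcpp::Named("index") = idx,
                            Rcpp::Named("distance") = dist);
}
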