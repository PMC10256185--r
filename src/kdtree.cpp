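// Static KD-tree for exact k-nearest-neighbor lookups over deduplicated dye
// tracks. Built once (median split on the widest-spread dimension), never
// edited afterwards. Queries return exact Euclidean nearest neighbors;
// kdtree_vote additionally aggregates Gaussian-kernel-weighted votes over the
// dye sequences that produced each neighboring track.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct KDNode {
  int left = -1, right = -1;   // children; -1 marks a leaf
  int lo = 0, hi = 0;          // range in perm (leaf only)
  int dim = 0;
  double split = 0.0;
};

struct KDTree {
  arma::mat pts;               // d x n (points in columns)
  std::vector<int> perm;
  std::vector<KDNode> nodes;
  int leaf_size = 24;

  int build(int lo, int hi) {
    KDNode node;
    if (hi - lo <= leaf_size) {
      node.lo = lo; node.hi = hi;
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    const int d = pts.n_rows;
    arma::vec mn(d, arma::fill::value(arma::datum::inf));
    arma::vec mx(d, arma::fill::value(-arma::datum::inf));
    for (int i = lo; i < hi; ++i) {
      for (int j = 0; j < d; ++j) {
        double v = pts(j, perm[i]);
        if (v < mn(j)) mn(j) = v;
        if (v > mx(j)) mx(j) = v;
      }
    }
    int dim = (int)(mx - mn).index_max();
    if (mx(dim) == mn(dim)) {  // all points identical on every dimension
      node.lo = lo; node.hi = hi;
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) { return pts(dim, a) < pts(dim, b); });
    node.dim = dim;
    node.split = pts(dim, perm[mid]);
    int self = (int)nodes.size();
    nodes.push_back(node);
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

// max-heap entry: (squared distance, point index); ties resolved toward the
// lower point index for deterministic results
typedef std::pair<double, int> HeapEntry;

static void query_node(const KDTree& tree, int ni, const double* q, int k,
                       std::priority_queue<HeapEntry>& heap) {
  const KDNode& node = tree.nodes[ni];
  const int d = tree.pts.n_rows;
  if (node.left < 0) {
    for (int i = node.lo; i < node.hi; ++i) {
      int idx = tree.perm[i];
      const double* p = tree.pts.colptr(idx);
      double d2 = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = q[j] - p[j];
        d2 += diff * diff;
      }
      HeapEntry e(d2, idx);
      if ((int)heap.size() < k) {
        heap.push(e);
      } else if (e < heap.top()) {
        heap.pop();
        heap.push(e);
      }
    }
    return;
  }
  double diff = q[node.dim] - node.split;
  int near = diff <= 0 ? node.left : node.right;
  int far = diff <= 0 ? node.right : node.left;
  query_node(tree, near, q, k, heap);
  if ((int)heap.size() < k || diff * diff <= heap.top().first) {
    query_node(tree, far, q, k, heap);
  }
}

static std::vector<HeapEntry> knn_sorted(const KDTree& tree, const double* q,
                                         int k) {
  std::priority_queue<HeapEntry> heap;
  query_node(tree, 0, q, k, heap);
  std::vector<HeapEntry> res(heap.size());
  for (int i = (int)heap.size() - 1; i >= 0; --i) {
    res[i] = heap.top();
    heap.pop();
  }
  return res;
}

// [[Rcpp::export]]
SEXP kdtree_build(const arma::mat& points) {
  KDTree* tree = new KDTree();
  tree->pts = points.t();   // store d x n
  tree->perm.resize(points.n_rows);
  for (size_t i = 0; i < points.n_rows; ++i) tree->perm[i] = (int)i;
  tree->build(0, (int)points.n_rows);
  XPtr<KDTree> ptr(tree, true);
  return ptr;
}

// [[Rcpp::export]]
int kdtree_size(SEXP ptr) {
  XPtr<KDTree> tree(ptr);
  return tree->pts.n_cols;
}

// [[Rcpp::export]]
List kdtree_query(SEXP ptr, const arma::mat& queries, int k) {
  XPtr<KDTree> tree(ptr);
  const int n_q = queries.n_rows;
  const int n_pts = tree->pts.n_cols;
  if ((int)queries.n_cols != (int)tree->pts.n_rows)
    stop("query dimension does not match index");
  int keff = std::min(k, n_pts);
  IntegerMatrix idx(n_q, keff);
  NumericMatrix dist(n_q, keff);
  arma::rowvec qr;
  for (int r = 0; r < n_q; ++r) {
    qr = queries.row(r);
    std::vector<HeapEntry> res = knn_sorted(*tree, qr.memptr(), keff);
    for (int i = 0; i < keff; ++i) {
      idx(r, i) = res[i].second + 1;
      dist(r, i) = std::sqrt(res[i].first);
    }
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}

// [[Rcpp::export]]
List kdtree_vote(SEXP ptr, const arma::mat& queries, int k, double sigma,
                 const arma::ivec& vote_ptr,   // CSC offsets per entry (0-based)
                 const arma::ivec& vote_id,    // 1..n_ids
                 const arma::vec& vote_cnt,
                 int n_ids, int hcap) {
  XPtr<KDTree> tree(ptr);
  const int n_q = queries.n_rows;
  const int n_pts = tree->pts.n_cols;
  if ((int)queries.n_cols != (int)tree->pts.n_rows)
    stop("query dimension does not match index");
  int keff = std::min(k, n_pts);
  IntegerMatrix ids(n_q, hcap);
  NumericMatrix wts(n_q, hcap);
  NumericVector total(n_q);
  std::vector<double> acc(n_ids, 0.0);
  std::vector<char> seen(n_ids, 0);
  std::vector<int> touched;
  touched.reserve(n_ids);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  arma::rowvec qr;
  for (int r = 0; r < n_q; ++r) {
    qr = queries.row(r);
    std::vector<HeapEntry> res = knn_sorted(*tree, qr.memptr(), keff);
    for (const HeapEntry& e : res) {
      double kern = std::exp(-e.first * inv2s2);
      int entry = e.second;
      for (int v = vote_ptr(entry); v < vote_ptr(entry + 1); ++v) {
        int id = vote_id(v) - 1;
        if (!seen[id]) { seen[id] = 1; touched.push_back(id); }
        acc[id] += vote_cnt(v) * kern;
      }
    }
    // rank voted ids by weight (desc), id (asc)
    std::sort(touched.begin(), touched.end(), [&](int a, int b) {
      if (acc[a] != acc[b]) return acc[a] > acc[b];
      return a < b;
    });
    double tot = 0.0;
    for (int id : touched) tot += acc[id];
    total(r) = tot;
    int m = std::min((int)touched.size(), hcap);
    for (int i = 0; i < m; ++i) {
      ids(r, i) = touched[i] + 1;
      wts(r, i) = acc[touched[i]];
    }
    for (int id : touched) { acc[id] = 0.0; seen[id] = 0; }
    touched.clear();
  }
  return List::create(Named("ids") = ids, Named("wts") = wts,
                      Named("total") = total);
}
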