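// Regression-tree engine shared by the CART forest and the gradient booster,
// plus the exact path-dependent Shapley explainer.
//
// Trees are grown on (gradient, hessian) statistics so a single split search
// serves both modes: for plain CART pass g = -y, h = 1, lambda = 0, gamma = 0,
// which makes the leaf value -G/(H+lambda) the node mean of y and the gain
// proportional to the SSE reduction (identical argmax).
//
// Missing values (NaN) are routed natively: at every split both directions are
// scored for the missing rows and the better one is stored as the node's
// default direction.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  bool missing_left = true;
  double value = 0.0;    // leaf value
  double cover = 0.0;    // training rows routed through the node
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& g;
  const NumericVector& h;
  int max_depth;
  int min_leaf;
  int mtry;
  double lambda;
  double gamma;
  std::mt19937 rng;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const NumericVector& g_,
         const NumericVector& h_, int max_depth_, int min_leaf_, int mtry_,
         double lambda_, double gamma_, uint32_t seed)
      : X(X_), g(g_), h(h_), max_depth(max_depth_), min_leaf(min_leaf_),
        mtry(mtry_), lambda(lambda_), gamma(gamma_), rng(seed) {}

  std::vector<int> sample_features() {
    const int p = X.ncol();
    std::vector<int> idx(p);
    for (int i = 0; i < p; ++i) idx[i] = i;
    if (mtry >= p) return idx;
    for (int i = 0; i < mtry; ++i) {
      int j = i + static_cast<int>(rng() % static_cast<uint32_t>(p - i));
      std::swap(idx[i], idx[j]);
    }
    idx.resize(mtry);
    std::sort(idx.begin(), idx.end());  // ascending: ties break to lowest index
    return idx;
  }

  int build(std::vector<int>& rows, int depth) {
    const int n = static_cast<int>(rows.size());
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }

    Node node;
    node.cover = n;
    node.value = -G / (H + lambda);

    bool can_split = depth < max_depth && n >= 2 * min_leaf;
    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;
    bool best_miss_left = true;
    const double parent_score = 0.5 * G * G / (H + lambda);
    // absolute floor guards against accepting pure round-off "gains"
    const double tol = 1e-10 * (std::fabs(parent_score) + 1e-8);

    if (can_split) {
      std::vector<int> cand = sample_features();
      std::vector<std::pair<double, int>> present;
      present.reserve(n);
      for (int f : cand) {
        present.clear();
        double Gm = 0.0, Hm = 0.0;
        int nm = 0;
        for (int r : rows) {
          double v = X(r, f);
          if (std::isnan(v)) { Gm += g[r]; Hm += h[r]; ++nm; }
          else present.emplace_back(v, r);
        }
        const int np = static_cast<int>(present.size());
        if (np < 2) continue;
        std::sort(present.begin(), present.end());
        double GL0 = 0.0, HL0 = 0.0;
        for (int i = 0; i + 1 < np; ++i) {
          GL0 += g[present[i].second];
          HL0 += h[present[i].second];
          if (!(present[i].first < present[i + 1].first)) continue;
          double thr = 0.5 * (present[i].first + present[i + 1].first);
          if (!(thr > present[i].first)) thr = present[i + 1].first;
          const int ndir = nm > 0 ? 2 : 1;
          for (int d = 0; d < ndir; ++d) {
            const bool miss_left = (d == 0);
            int nl = (i + 1) + (miss_left ? nm : 0);
            int nr = n - nl;
            if (nl < min_leaf || nr < min_leaf) continue;
            double GL = GL0 + (miss_left ? Gm : 0.0);
            double HL = HL0 + (miss_left ? Hm : 0.0);
            double GR = G - GL, HR = H - HL;
            double gain = 0.5 * (GL * GL / (HL + lambda) +
                                 GR * GR / (HR + lambda)) -
                          parent_score - gamma;
            if (gain > best_gain && gain > tol) {
              best_gain = gain;
              best_f = f;
              best_thr = thr;
              best_miss_left = miss_left;
            }
          }
        }
      }
    }

    int self = static_cast<int>(nodes.size());
    nodes.push_back(node);
    if (best_f < 0) return self;

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int r : rows) {
      double v = X(r, best_f);
      bool left = std::isnan(v) ? best_miss_left : (v < best_thr);
      (left ? lrows : rrows).push_back(r);
    }
    // release parent's copy early
    std::vector<int>().swap(rows);
    nodes[self].feature = best_f;
    nodes[self].threshold = best_thr;
    nodes[self].missing_left = best_miss_left;
    int l = build(lrows, depth + 1);
    int r = build(rrows, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

List nodes_to_list(const std::vector<Node>& nodes) {
  const int m = static_cast<int>(nodes.size());
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m), cover(m);
  LogicalVector missing_left(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    missing_left[i] = nodes[i].missing_left;
    value[i] = nodes[i].value;
    cover[i] = nodes[i].cover;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["missing_left"] = missing_left, _["value"] = value,
                      _["cover"] = cover);
}

struct FlatTree {
  IntegerVector feature, left, right;
  NumericVector threshold, value, cover;
  LogicalVector missing_left;
  explicit FlatTree(const List& t)
      : feature(t["feature"]), left(t["left"]), right(t["right"]),
        threshold(t["threshold"]), value(t["value"]), cover(t["cover"]),
        missing_left(t["missing_left"]) {}
  bool leaf(int i) const { return feature[i] < 0; }
  // child the row x is routed to at internal node i
  int route(int i, const NumericVector& x) const {
    double v = x[feature[i]];
    bool go_left = std::isnan(v) ? static_cast<bool>(missing_left[i])
                                 : (v < threshold[i]);
    return go_left ? left[i] : right[i];
  }
};

double leaf_mean_rec(const FlatTree& t, int i) {
  if (t.leaf(i)) return t.value[i];
  if (t.cover[i] <= 0) stop("malformed model: internal node with zero cover");
  double wl = t.cover[t.left[i]] / t.cover[i];
  return wl * leaf_mean_rec(t, t.left[i]) +
         (1.0 - wl) * leaf_mean_rec(t, t.right[i]);
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector g, NumericVector h,
                   IntegerVector rows, int max_depth, int min_leaf, int mtry,
                   double lambda, double gamma, int seed) {
  if (rows.size() == 0) stop("cannot grow a tree on zero rows");
  Grower gr(X, g, h, max_depth, min_leaf, mtry, lambda, gamma,
            static_cast<uint32_t>(seed));
  std::vector<int> r(rows.begin(), rows.end());  // already 0-based
  gr.build(r, 0);
  return nodes_to_list(gr.nodes);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  FlatTree t(tree);
  const int n = X.nrow();
  NumericVector out(n);
  NumericVector x(X.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < X.ncol(); ++j) x[j] = X(i, j);
    int node = 0;
    while (!t.leaf(node)) node = t.route(node, x);
    out[i] = t.value[node];
  }
  return out;
}

namespace {
double path_exp_rec(const FlatTree& t, int node, const NumericVector& x,
                    const std::vector<char>& inS) {
  if (t.leaf(node)) return t.value[node];
  if (t.cover[node] <= 0)
    stop("malformed model: internal node with zero cover");
  if (inS[t.feature[node]]) return path_exp_rec(t, t.route(node, x), x, inS);
  double wl = t.cover[t.left[node]] / t.cover[node];
  return wl * path_exp_rec(t, t.left[node], x, inS) +
         (1.0 - wl) * path_exp_rec(t, t.right[node], x, inS);
}
}  // namespace

// Path-dependent conditional expectation v(S): features in S follow the row,
// features outside S average both children weighted by training cover.
// [[Rcpp::export]]
double cpp_path_expectation(List tree, NumericVector x, IntegerVector S) {
  FlatTree t(tree);
  std::vector<char> inS(x.size(), 0);
  for (int j : S) {
    if (j < 0 || j >= static_cast<int>(x.size()))
      stop("feature index out of range");
    inS[j] = 1;
  }
  return path_exp_rec(t, 0, x, inS);
}

namespace {

// Shapley weights w(m, k) = k! (m-1-k)! / m! = 1 / (m * choose(m-1, k))
struct ShapWeights {
  std::vector<std::vector<double>> w;
  explicit ShapWeights(int maxm) : w(maxm + 1) {
    for (int m = 1; m <= maxm; ++m) {
      w[m].resize(m);
      double ch = 1.0;  // choose(m-1, k)
      for (int k = 0; k < m; ++k) {
        w[m][k] = 1.0 / (m * ch);
        ch = ch * (m - 1 - k) / (k + 1);
      }
    }
  }
};

// Exact Shapley values for one tree and one row.
//
// The path-dependent game v(S) decomposes over leaves: each leaf L with value
// c contributes a multiplicative game  u(S) = c * prod_{j in F_L} (j in S ?
// a_j : r_j)  where F_L are the distinct features on its path, a_j indicates
// whether the row's routing agrees with every j-split on the path, and r_j is
// the product of cover fractions of the path's children at the j-splits.  The
// Shapley value of such a game has the closed form
//   phi_j = c (a_j - r_j) sum_k w(m,k) [z^k] prod_{l != j} (r_l + a_l z),
// evaluated here by building the product polynomial once per leaf and
// deflating it for each feature. Identical to full subset enumeration, but
// polynomial in path depth.
struct ShapWalker {
  const FlatTree& t;
  const NumericVector& x;
  const ShapWeights& W;
  std::vector<char> a;      // per feature: routing consistent so far
  std::vector<double> r;    // per feature: product of cover fractions
  std::vector<int> cnt;     // per feature: occurrences on current path
  std::vector<int> onpath;  // features with cnt > 0
  std::vector<double> phi;
  std::vector<double> poly, q;

  ShapWalker(const FlatTree& t_, const NumericVector& x_,
             const ShapWeights& W_)
      : t(t_), x(x_), W(W_), a(x_.size(), 1), r(x_.size(), 1.0),
        cnt(x_.size(), 0), phi(x_.size(), 0.0) {}

  void leaf_contrib(double c) {
    const int m = static_cast<int>(onpath.size());
    if (m == 0) return;  // root is a leaf: constant game, all phi zero
    poly.assign(m + 1, 0.0);
    poly[0] = 1.0;
    for (int jj = 0; jj < m; ++jj) {
      int f = onpath[jj];
      double aj = a[f] ? 1.0 : 0.0, rj = r[f];
      for (int k = jj + 1; k >= 1; --k) poly[k] = rj * poly[k] + aj * poly[k - 1];
      poly[0] *= rj;
    }
    q.assign(m, 0.0);
    const std::vector<double>& w = W.w[m];
    for (int jj = 0; jj < m; ++jj) {
      int f = onpath[jj];
      double aj = a[f] ? 1.0 : 0.0, rj = r[f];
      if (aj != 0.0) {
        q[m - 1] = poly[m] / aj;
        for (int k = m - 1; k >= 1; --k) q[k - 1] = (poly[k] - rj * q[k]) / aj;
      } else {
        for (int k = 0; k < m; ++k) q[k] = poly[k] / rj;
      }
      double s = 0.0;
      for (int k = 0; k < m; ++k) s += w[k] * q[k];
      phi[f] += c * (aj - rj) * s;
    }
  }

  void walk(int node) {
    if (t.leaf(node)) { leaf_contrib(t.value[node]); return; }
    if (t.cover[node] <= 0)
      stop("malformed model: internal node with zero cover");
    const int f = t.feature[node];
    const int routed = t.route(node, x);
    const char a_old = a[f];
    const double r_old = r[f];
    const int c_old = cnt[f];
    if (c_old == 0) onpath.push_back(f);
    for (int side = 0; side < 2; ++side) {
      int child = side == 0 ? t.left[node] : t.right[node];
      a[f] = a_old && (child == routed);
      r[f] = r_old * t.cover[child] / t.cover[node];
      cnt[f] = c_old + 1;
      walk(child);
    }
    a[f] = a_old; r[f] = r_old; cnt[f] = c_old;
    if (c_old == 0) onpath.pop_back();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_tree_shap(List tree, NumericMatrix X) {
  FlatTree t(tree);
  const int n = X.nrow(), p = X.ncol();
  ShapWeights W(std::max(p, 1));
  NumericMatrix phi(n, p);
  NumericVector x(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    ShapWalker wlk(t, x, W);
    wlk.walk(0);
    for (int j = 0; j < p; ++j) phi(i, j) = wlk.phi[j];
  }
  return List::create(_["phi"] = phi, _["phi0"] = leaf_mean_rec(t, 0));
}
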