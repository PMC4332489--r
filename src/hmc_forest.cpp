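// Hierarchical multi-label classification forest core.
//
// Trees split binary genome-presence features to minimize the
// hierarchy-weighted class-vector variance
//   Var(S) = (1/|S|) * sum_i sum_c w_c * (v_ic - mean_c)^2
// Leaves store the mean class vector of in-leaf training examples.
// All randomness comes from a self-contained splitmix64 generator so a
// (seed, tree index) pair fully determines a tree on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

uint64_t spawn_seed(uint64_t master, uint64_t stream) {
  SplitMix mix(master ^ (0xA5A5A5A55A5A5A5AULL + stream * 0x9E3779B97F4A7C15ULL));
  return mix.next();
}

// weighted variance of the class vectors indexed by idx, times n (SSE form)
// returns sum_c w_c * (sumsq_c - sum_c^2 / n)
double node_sse(const NumericMatrix& V, const NumericVector& w,
                const std::vector<int>& idx) {
  const int L = V.ncol();
  const double n = static_cast<double>(idx.size());
  double sse = 0.0;
  for (int c = 0; c < L; ++c) {
    double s = 0.0, q = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) {
      const double v = V(idx[k], c);
      s += v;
      q += v * v;
    }
    sse += w[c] * (q - s * s / n);
  }
  return sse;
}

struct SplitResult {
  int feature;   // -1 when no valid split
  double gain;   // variance reduction (per-example scale)
};

// best split over the given candidate features (ascending order assumed;
// ties broken by the first, i.e. lowest-index, candidate)
SplitResult best_split_impl(const IntegerMatrix& X, const NumericMatrix& V,
                            const NumericVector& w,
                            const std::vector<int>& idx,
                            const std::vector<int>& candidates,
                            int min_leaf) {
  const int L = V.ncol();
  const double n = static_cast<double>(idx.size());
  const double parent_sse = node_sse(V, w, idx);
  // node totals, shared by every candidate: sse0 = total minus side-1 parts
  std::vector<double> stot(L, 0.0), qtot(L, 0.0);
  for (size_t k = 0; k < idx.size(); ++k)
    for (int c = 0; c < L; ++c) {
      const double v = V(idx[k], c);
      stot[c] += v;
      qtot[c] += v * v;
    }
  SplitResult best{-1, 0.0};
  std::vector<double> s1(L), q1(L);
  for (size_t ci = 0; ci < candidates.size(); ++ci) {
    const int f = candidates[ci];
    int n1 = 0;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(q1.begin(), q1.end(), 0.0);
    for (size_t k = 0; k < idx.size(); ++k) {
      if (X(idx[k], f) == 1) {
        ++n1;
        for (int c = 0; c < L; ++c) {
          const double v = V(idx[k], c);
          s1[c] += v;
          q1[c] += v * v;
        }
      }
    }
    const int n0 = static_cast<int>(idx.size()) - n1;
    if (n0 < min_leaf || n1 < min_leaf) continue;
    double child_sse = 0.0;
    for (int c = 0; c < L; ++c) {
      const double s0c = stot[c] - s1[c];
      const double q0c = qtot[c] - q1[c];
      child_sse += w[c] * (q0c - s0c * s0c / n0);
      child_sse += w[c] * (q1[c] - s1[c] * s1[c] / n1);
    }
    const double gain = (parent_sse - child_sse) / n;
    if (gain > best.gain && gain > 0.0) {
      best.feature = f;
      best.gain = gain;
    }
  }
  return best;
}

struct TreeBuilder {
  const IntegerMatrix& X;
  const NumericMatrix& V;
  const NumericVector& w;
  int mtry, min_leaf, p;
  SplitMix rng;
  std::vector<int> feature, left, right, leaf_of;
  std::vector<std::vector<double> > leaves;

  TreeBuilder(const IntegerMatrix& X_, const NumericMatrix& V_,
              const NumericVector& w_, int mtry_, int min_leaf_, uint64_t seed)
      : X(X_), V(V_), w(w_), mtry(mtry_), min_leaf(min_leaf_),
        p(X_.ncol()), rng(seed) {}

  // draw mtry distinct features, returned sorted ascending
  std::vector<int> draw_candidates() {
    std::vector<int> pool(p);
    for (int i = 0; i < p; ++i) pool[i] = i;
    const int m = mtry < p ? mtry : p;
    for (int i = 0; i < m; ++i) {
      const int j = i + rng.below(p - i);
      std::swap(pool[i], pool[j]);
    }
    std::vector<int> cand(pool.begin(), pool.begin() + m);
    std::sort(cand.begin(), cand.end());
    return cand;
  }

  int make_leaf(const std::vector<int>& idx) {
    const int L = V.ncol();
    std::vector<double> mean(L, 0.0);
    for (size_t k = 0; k < idx.size(); ++k)
      for (int c = 0; c < L; ++c) mean[c] += V(idx[k], c);
    for (int c = 0; c < L; ++c) mean[c] /= static_cast<double>(idx.size());
    leaves.push_back(mean);
    const int node = static_cast<int>(feature.size());
    feature.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    leaf_of.push_back(static_cast<int>(leaves.size()) - 1);
    return node;
  }

  int grow(const std::vector<int>& idx) {
    if (static_cast<int>(idx.size()) < 2 * min_leaf) return make_leaf(idx);
    const std::vector<int> cand = draw_candidates();
    const SplitResult sp = best_split_impl(X, V, w, idx, cand, min_leaf);
    if (sp.feature < 0) return make_leaf(idx);
    std::vector<int> idx0, idx1;
    for (size_t k = 0; k < idx.size(); ++k) {
      if (X(idx[k], sp.feature) == 1) idx1.push_back(idx[k]);
      else idx0.push_back(idx[k]);
    }
    const int node = static_cast<int>(feature.size());
    feature.push_back(sp.feature);
    left.push_back(-2);   // patched below
    right.push_back(-2);
    leaf_of.push_back(-1);
    const int l = grow(idx0);
    const int r = grow(idx1);
    left[node] = l;
    right[node] = r;
    return node;
  }

  List as_list() const {
    const int L = V.ncol();
    NumericMatrix leaf_mat(static_cast<int>(leaves.size()), L);
    for (size_t i = 0; i < leaves.size(); ++i)
      for (int c = 0; c < L; ++c) leaf_mat(static_cast<int>(i), c) = leaves[i][c];
    return List::create(_["feature"] = IntegerVector(feature.begin(), feature.end()),
                        _["left"] = IntegerVector(left.begin(), left.end()),
                        _["right"] = IntegerVector(right.begin(), right.end()),
                        _["leaf_of"] = IntegerVector(leaf_of.begin(), leaf_of.end()),
                        _["leaves"] = leaf_mat);
  }
};

// index (0-based) of the leaf matrix row example i falls into
int traverse(const List& tree, const IntegerMatrix& X, int i) {
  IntegerVector feature = tree["feature"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  IntegerVector leaf_of = tree["leaf_of"];
  int node = 0;
  while (feature[node] >= 0)
    node = (X(i, feature[node]) == 1) ? right[node] : left[node];
  return leaf_of[node];
}

}  // namespace

// [[Rcpp::export(name = ".cpp_weighted_variance")]]
double cpp_weighted_variance(NumericMatrix V, NumericVector w) {
  if (V.nrow() == 0) stop("need at least one class vector");
  if (V.ncol() != w.size()) stop("weight length must match term count");
  std::vector<int> idx(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) idx[i] = i;
  return node_sse(V, w, idx) / static_cast<double>(V.nrow());
}

// [[Rcpp::export(name = ".cpp_best_split")]]
List cpp_best_split(IntegerMatrix X, NumericMatrix V, NumericVector w,
                    IntegerVector candidates, int min_leaf) {
  if (candidates.size() == 0) stop("candidate feature set must be non-empty");
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  std::sort(cand.begin(), cand.end());
  for (size_t i = 0; i < cand.size(); ++i)
    if (cand[i] < 0 || cand[i] >= X.ncol()) stop("candidate feature out of range");
  const SplitResult sp = best_split_impl(X, V, w, idx, cand, min_leaf);
  return List::create(_["feature"] = sp.feature, _["gain"] = sp.gain);
}

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(IntegerMatrix X, NumericMatrix V, NumericVector w,
                   int mtry, int min_leaf, double seed) {
  TreeBuilder tb(X, V, w, mtry, min_leaf, static_cast<uint64_t>(seed));
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  tb.grow(idx);
  return tb.as_list();
}

// [[Rcpp::export(name = ".cpp_fit_forest")]]
List cpp_fit_forest(IntegerMatrix X, NumericMatrix V, NumericVector w,
                    int n_trees, int mtry, int min_leaf, double seed) {
  const int n = X.nrow();
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  for (int t = 0; t < n_trees; ++t) {
    SplitMix bag_rng(spawn_seed(static_cast<uint64_t>(seed), 2 * t));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      const int j = bag_rng.below(n);
      idx[i] = j;
      inbag(j, t) += 1;
    }
    TreeBuilder tb(X, V, w, mtry, min_leaf,
                   spawn_seed(static_cast<uint64_t>(seed), 2 * t + 1));
    tb.grow(idx);
    trees[t] = tb.as_list();
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".cpp_predict")]]
NumericMatrix cpp_predict(List trees, IntegerMatrix X, IntegerMatrix inbag,
                          bool oob_only, IntegerVector coverage_out) {
  const int n = X.nrow();
  const int T = trees.size();
  List tree0 = trees[0];
  NumericMatrix leaves0 = tree0["leaves"];
  const int L = leaves0.ncol();
  NumericMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    int cover = 0;
    for (int t = 0; t < T; ++t) {
      if (oob_only && inbag(i, t) > 0) continue;
      List tree = trees[t];
      NumericMatrix leaves = tree["leaves"];
      const int leaf = traverse(tree, X, i);
      for (int c = 0; c < L; ++c) out(i, c) += leaves(leaf, c);
      ++cover;
    }
    if (cover > 0)
      for (int c = 0; c < L; ++c) out(i, c) /= static_cast<double>(cover);
    else
      for (int c = 0; c < L; ++c) out(i, c) = NA_REAL;
    coverage_out[i] = cover;
  }
  return out;
}
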