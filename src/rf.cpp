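// Random forest classifier: bagged, unpruned Gini CART trees with a random
// feature subset of size mtry at every node. Single-threaded and fully
// deterministic under the supplied seed (own xorshift RNG; R's RNG state is
// never touched). Trees are returned as flat numeric matrices so models are
// plain R lists and serialize with saveRDS.
//
// Tree node row layout (columns):
//   0 feature (0-based; -1 for leaf)
//   1 threshold (go left if x <= thr)
//   2 left child row (0-based)
//   3 right child row
//   4 leaf value (fraction of positive training rows in the leaf)

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {  // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  uint32_t unif(uint32_t n) { return (uint32_t)(next() % n); }
};

struct Node {
  int feature = -1;
  float thr = 0.f;
  int left = -1, right = -1;
  float value = 0.f;
};

struct Job { int begin, end, node; };

void build_tree(const arma::fmat& X, const std::vector<int>& y,
                std::vector<int>& idx, int mtry, int min_node, Rng& rng,
                std::vector<Node>& nodes) {
  const int p = X.n_cols;
  std::vector<int> feats(p);
  std::vector<std::pair<float, int>> buf;
  nodes.clear();
  nodes.push_back(Node());
  std::vector<Job> stack;
  stack.push_back({0, (int)idx.size(), 0});

  while (!stack.empty()) {
    Job job = stack.back();
    stack.pop_back();
    const int sz = job.end - job.begin;
    int pos = 0;
    for (int k = job.begin; k < job.end; ++k) pos += y[idx[k]];
    nodes[job.node].value = (float)pos / sz;
    if (sz < 2 * min_node || pos == 0 || pos == sz) continue;  // pure/small leaf

    // sample mtry candidate features without replacement (partial Fisher-Yates)
    for (int f = 0; f < p; ++f) feats[f] = f;
    int best_f = -1, best_cut = -1;
    float best_thr = 0.f;
    double best_score = -1.0;  // sum of weighted child purities, higher better
    for (int t = 0; t < mtry; ++t) {
      int r = t + rng.unif(p - t);
      std::swap(feats[t], feats[r]);
      const int f = feats[t];
      buf.resize(sz);
      for (int k = 0; k < sz; ++k) {
        int i = idx[job.begin + k];
        buf[k] = {X(i, f), y[i]};
      }
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;  // constant
      // scan split points between distinct values
      int lp = 0;
      for (int k = 0; k < sz - 1; ++k) {
        lp += buf[k].second;
        if (buf[k].first == buf[k + 1].first) continue;
        int ln = k + 1, rn = sz - ln, rp = pos - lp;
        // Gini decrease maximization == maximize sum over children of
        // (pos^2 + neg^2)/n_child
        double score =
            ((double)lp * lp + (double)(ln - lp) * (ln - lp)) / ln +
            ((double)rp * rp + (double)(rn - rp) * (rn - rp)) / rn;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_cut = k;
          best_thr = 0.5f * (buf[k].first + buf[k + 1].first);
          // guard against midpoint rounding to the upper value
          if (!(best_thr > buf[k].first)) best_thr = buf[k].first;
        }
      }
    }
    if (best_f < 0) continue;  // no usable split among candidates -> leaf

    // parent purity; only split if it strictly improves (ties allowed for
    // pure-child splits, which always improve unless parent already pure)
    double parent = ((double)pos * pos + (double)(sz - pos) * (sz - pos)) / sz;
    if (best_score <= parent + 1e-12) continue;

    // partition idx in place: x <= thr left
    int mid = job.begin;
    for (int k = job.begin; k < job.end; ++k)
      if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);

    const int li = (int)nodes.size();
    nodes.push_back(Node());
    const int ri = (int)nodes.size();
    nodes.push_back(Node());  // may reallocate: index, don't hold references
    nodes[job.node].feature = best_f;
    nodes[job.node].thr = best_thr;
    nodes[job.node].left = li;
    nodes[job.node].right = ri;
    stack.push_back({job.begin, mid, li});
    stack.push_back({mid, job.end, ri});
  }
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix M(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    M(i, 0) = nodes[i].feature;
    M(i, 1) = nodes[i].thr;
    M(i, 2) = nodes[i].left;
    M(i, 3) = nodes[i].right;
    M(i, 4) = nodes[i].value;
  }
  return M;
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(const arma::mat& Xd, const IntegerVector& y, int n_trees,
                  int mtry, double seed, int min_node = 1) {
  const int n = Xd.n_rows;
  arma::fmat X = arma::conv_to<arma::fmat>::from(Xd);
  std::vector<int> yy(y.begin(), y.end());
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  List forest(n_trees);
  std::vector<int> idx(n);
  std::vector<Node> nodes;
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.unif(n);  // bootstrap sample
    build_tree(X, yy, idx, mtry, min_node, rng, nodes);
    forest[t] = pack_tree(nodes);
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return forest;
}

// Score = fraction of trees voting positive (leaf value > 0.5 counts 1,
// == 0.5 counts 0.5), i.e. a soft majority vote over the ensemble.
// [[Rcpp::export]]
NumericVector rf_predict_cpp(const List& forest, const arma::mat& Xd) {
  arma::fmat X = arma::conv_to<arma::fmat>::from(Xd);
  const int n = X.n_rows, T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (M(node, 0) >= 0) {
        int f = (int)M(node, 0);
        node = (X(i, f) <= (float)M(node, 1)) ? (int)M(node, 2)
                                              : (int)M(node, 3);
      }
      double v = M(node, 4);
      out[i] += (v > 0.5) ? 1.0 : (v == 0.5 ? 0.5 : 0.0);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
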