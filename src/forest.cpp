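#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Deterministic uniform integer in [0, k). Uses the raw mt19937 stream with a
// modulo reduction: the bias is < k / 2^32 and, unlike std::uniform_int_distribution,
// the result is identical across standard library implementations.
static inline int runif_int(std::mt19937 &rng, int k) {
  return static_cast<int>(rng() % static_cast<uint32_t>(k));
}

// A single CART-style classification tree grown to purity (no pruning), with
// mtry features sampled without replacement at every node and Gini-impurity
// split selection. Nodes are stored in parallel arrays; leaves keep the
// positive-class fraction of their bag sample.
struct TreeBuilder {
  const NumericMatrix &X;
  std::vector<int> rows;   // bag row indices into X (permuted in place)
  std::vector<int> y;      // parallel 0/1 labels
  int mtry, min_node, p;
  std::mt19937 &rng;
  std::vector<double> feat, thr, pred;
  std::vector<double> left, right;
  std::vector<int> featbuf;

  TreeBuilder(const NumericMatrix &X_, std::vector<int> rows_, std::vector<int> y_,
              int mtry_, int min_node_, std::mt19937 &rng_)
    : X(X_), rows(rows_), y(y_), mtry(mtry_), min_node(min_node_),
      p(X_.ncol()), rng(rng_) {
    featbuf.resize(p);
    for (int j = 0; j < p; j++) featbuf[j] = j;
  }

  // builds the subtree for rows[lo, hi); returns its node id
  int build(int lo, int hi) {
    int n = hi - lo, npos = 0;
    for (int i = lo; i < hi; i++) npos += y[i];
    int id = static_cast<int>(feat.size());
    feat.push_back(-1.0); thr.push_back(0.0);
    left.push_back(-1.0); right.push_back(-1.0);
    pred.push_back(static_cast<double>(npos) / n);
    if (npos == 0 || npos == n || n < 2 * min_node || n < 2) return id;

    // partial Fisher-Yates: the first mtry entries of featbuf become the candidate set
    for (int i = 0; i < mtry; i++) {
      int j = i + runif_int(rng, p - i);
      std::swap(featbuf[i], featbuf[j]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_score = 1e300;
    std::vector<std::pair<double,int>> v(n);
    for (int fi = 0; fi < mtry; fi++) {
      int f = featbuf[fi];
      for (int i = 0; i < n; i++)
        v[i] = std::make_pair(X(rows[lo + i], f), y[lo + i]);
      std::sort(v.begin(), v.end());
      int lpos = 0;
      for (int k = 1; k < n; k++) {
        lpos += v[k - 1].second;
        if (v[k].first <= v[k - 1].first) continue;  // cannot split inside ties
        int rpos = npos - lpos, nr = n - k;
        // weighted Gini: sum over children of n_pos * n_neg / n_child (x2 constant dropped)
        double score = static_cast<double>(lpos) * (k - lpos) / k
                     + static_cast<double>(rpos) * (nr - rpos) / nr;
        if (score < best_score - 1e-12) {
          best_score = score;
          best_f = f;
          best_thr = (v[k - 1].first + v[k].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return id;  // all candidate features constant: leaf

    // partition rows/y in place around the threshold
    int mid = lo;
    for (int i = lo; i < hi; i++) {
      if (X(rows[i], best_f) <= best_thr) {
        std::swap(rows[i], rows[mid]);
        std::swap(y[i], y[mid]);
        mid++;
      }
    }
    feat[id] = best_f; thr[id] = best_thr;
    int l = build(lo, mid);
    int r = build(mid, hi);
    left[id] = l; right[id] = r;
    return id;
  }

  NumericMatrix as_matrix() const {
    int m = static_cast<int>(feat.size());
    NumericMatrix out(m, 5);
    for (int i = 0; i < m; i++) {
      out(i, 0) = feat[i]; out(i, 1) = thr[i];
      out(i, 2) = left[i]; out(i, 3) = right[i];
      out(i, 4) = pred[i];
    }
    colnames(out) = CharacterVector::create("feature", "threshold", "left", "right", "pred");
    return out;
  }
};

static double predict_row(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = static_cast<int>(tree(node, 0));
    node = static_cast<int>(X(row, f) <= tree(node, 1) ? tree(node, 2) : tree(node, 3));
  }
  return tree(node, 4);
}

// Class-balanced bagged forest: per tree, positives are bootstrapped (n_pos draws
// with replacement) and negatives are drawn without replacement to match, then a
// tree is grown on the bag. Every row of X is scored by every tree; rows absent
// from a tree's bag additionally contribute to that tree's out-of-bag tallies.
// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector pos_idx, IntegerVector neg_idx,
                  int ntree, int mtry, int min_node, int seed) {
  int n = X.nrow(), npos = pos_idx.size(), nneg = neg_idx.size();
  if (npos < 1 || nneg < 1) stop("both classes must be non-empty");
  std::mt19937 rng(static_cast<uint32_t>(seed));
  NumericVector vote_sum(n), oob_sum(n);
  IntegerVector oob_cnt(n);
  IntegerMatrix bag_sizes(ntree, 2);
  List trees(ntree);
  std::vector<char> inbag(n);
  int take = std::min(npos, nneg);

  for (int t = 0; t < ntree; t++) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> rows; rows.reserve(npos + take);
    std::vector<int> lab; lab.reserve(npos + take);
    for (int i = 0; i < npos; i++) {
      int r = pos_idx[runif_int(rng, npos)];
      rows.push_back(r); lab.push_back(1); inbag[r] = 1;
    }
    std::vector<int> negs(neg_idx.begin(), neg_idx.end());
    for (int i = 0; i < take; i++) {
      int j = i + runif_int(rng, nneg - i);
      std::swap(negs[i], negs[j]);
      rows.push_back(negs[i]); lab.push_back(0); inbag[negs[i]] = 1;
    }
    bag_sizes(t, 0) = npos; bag_sizes(t, 1) = take;

    TreeBuilder b(X, rows, lab, mtry, min_node, rng);
    b.build(0, static_cast<int>(rows.size()));
    NumericMatrix tm = b.as_matrix();
    trees[t] = tm;

    for (int i = 0; i < n; i++) {
      double pr = predict_row(tm, X, i);
      vote_sum[i] += pr;
      if (!inbag[i]) { oob_sum[i] += pr; oob_cnt[i]++; }
    }
  }
  return List::create(_["trees"] = trees,
                      _["vote_sum"] = vote_sum,
                      _["oob_sum"] = oob_sum,
                      _["oob_cnt"] = oob_cnt,
                      _["bag_sizes"] = bag_sizes,
                      _["ntree"] = ntree);
}

// Mean tree prediction (positive-class vote fraction) for new data.
// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; t++) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; i++) out[i] += predict_row(tm, X, i);
  }
  for (int i = 0; i < n; i++) out[i] /= ntree;
  return out;
}
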