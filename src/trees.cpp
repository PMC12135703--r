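// Minimal CART-style regression trees used as the shared primitive for the
// random-forest and gradient-boosting learners. Binary classification
// forests use 0/1 targets with variance splitting (equivalent to Gini for
// binary outcomes); boosting fits trees to gradient residuals.
//
// Randomness (bootstrap resampling, mtry feature subsampling) flows through
// R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;       // -1 for leaf
  std::vector<double> threshold;  // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;      // node mean of y
};

struct Node {
  int id;
  int start, end;  // range in the index buffer
  int depth;
};

// sample k of p feature indices without replacement (partial Fisher-Yates)
void sample_features(std::vector<int> &pool, int k) {
  int p = static_cast<int>(pool.size());
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
}

int build_tree(const NumericMatrix &X, const NumericVector &y,
               std::vector<int> &idx, int mtry, int min_leaf,
               int max_depth, TreeBuf &tb) {
  const int p = X.ncol();
  std::vector<int> pool(p);
  std::vector<std::pair<double, int> > vals;
  std::vector<Node> stack;

  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.value.push_back(0.0);
  Node root = {0, 0, static_cast<int>(idx.size()), 0};
  stack.push_back(root);

  while (!stack.empty()) {
    Node nd = stack.back();
    stack.pop_back();
    const int n = nd.end - nd.start;

    double sum = 0.0, sum2 = 0.0;
    for (int i = nd.start; i < nd.end; ++i) {
      sum += y[idx[i]];
      sum2 += y[idx[i]] * y[idx[i]];
    }
    tb.value[nd.id] = sum / n;
    const double node_sse = sum2 - sum * sum / n;

    bool can_split = n >= 2 * min_leaf && node_sse > 1e-12 &&
                     (max_depth < 0 || nd.depth < max_depth);
    if (!can_split) continue;

    for (int f = 0; f < p; ++f) pool[f] = f;
    sample_features(pool, mtry);

    int best_f = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    for (int fi = 0; fi < mtry; ++fi) {
      const int f = pool[fi];
      vals.clear();
      for (int i = nd.start; i < nd.end; ++i)
        vals.push_back(std::make_pair(X(idx[i], f), idx[i]));
      std::sort(vals.begin(), vals.end());
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += y[vals[i].second];
        const int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (vals[i].first >= vals[i + 1].first) continue;  // tied values
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr -
                            sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;

    // partition idx[start:end) on the chosen split
    int mid = nd.start;
    for (int i = nd.start; i < nd.end; ++i)
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);

    const int lid = static_cast<int>(tb.feature.size());
    const int rid = lid + 1;
    for (int k = 0; k < 2; ++k) {
      tb.feature.push_back(-1);
      tb.threshold.push_back(0.0);
      tb.left.push_back(-1);
      tb.right.push_back(-1);
      tb.value.push_back(0.0);
    }
    tb.feature[nd.id] = best_f;
    tb.threshold[nd.id] = best_thr;
    tb.left[nd.id] = lid;
    tb.right[nd.id] = rid;
    Node ln = {lid, nd.start, mid, nd.depth + 1};
    Node rn = {rid, mid, nd.end, nd.depth + 1};
    stack.push_back(ln);
    stack.push_back(rn);
  }
  return static_cast<int>(tb.feature.size());
}

List tree_to_list(const TreeBuf &tb) {
  return List::create(
      _["feature"] = wrap(tb.feature), _["threshold"] = wrap(tb.threshold),
      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
      _["value"] = wrap(tb.value));
}

inline int descend(const IntegerVector &feature, const NumericVector &thr,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= thr[node]) ? left[node] : right[node];
  return node;
}

}  // namespace

// [[Rcpp::export]]
List tree_fit_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int mtry, int min_leaf, int max_depth) {
  std::vector<int> idx(rows.begin(), rows.end());
  TreeBuf tb;
  build_tree(X, y, idx, mtry, min_leaf, max_depth, tb);
  return tree_to_list(tb);
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = value[descend(feature, thr, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector tree_leaf_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feature, thr, left, right, X, i);
  return out;
}

namespace {

// midrank AUROC over rows with at least one OOB vote
double auc_rank(const std::vector<double> &score,
                const std::vector<int> &label) {
  const int n = static_cast<int>(score.size());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  double n1 = 0, n0 = 0, rsum = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) ++j;
    const double midrank = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k)
      if (label[ord[k]]) rsum += midrank;
    i = j + 1;
  }
  for (int k = 0; k < n; ++k)
    if (label[k]) n1 += 1; else n0 += 1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1) / 2) / (n1 * n0);
}

struct FlatTree {
  std::vector<int> feature, left, right;
  std::vector<double> thr, value;
};

}  // namespace

// Breiman-style OOB permutation importance: mean OOB-AUROC drop over B
// within-column permutations, one value per requested column.
// [[Rcpp::export]]
NumericVector forest_perm_importance_cpp(List trees, List oob_rows,
                                         NumericMatrix X, IntegerVector y,
                                         IntegerVector cols, int B) {
  const int n = X.nrow();
  const int ntree = trees.size();
  std::vector<FlatTree> ft(ntree);
  for (int b = 0; b < ntree; ++b) {
    List tree = trees[b];
    IntegerVector fe = tree["feature"], le = tree["left"],
                  ri = tree["right"];
    NumericVector th = tree["threshold"], va = tree["value"];
    ft[b].feature.assign(fe.begin(), fe.end());
    ft[b].left.assign(le.begin(), le.end());
    ft[b].right.assign(ri.begin(), ri.end());
    ft[b].thr.assign(th.begin(), th.end());
    ft[b].value.assign(va.begin(), va.end());
  }

  // OOB aggregation with an optionally permuted column g (perm maps row ->
  // source row for that column; g < 0 disables)
  std::vector<double> sum(n);
  std::vector<int> cnt(n);
  std::vector<double> score;
  std::vector<int> label;
  std::vector<int> perm(n);

  auto oob_auc = [&](int g) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int b = 0; b < ntree; ++b) {
      const FlatTree &t = ft[b];
      IntegerVector oob = oob_rows[b];
      for (int k = 0; k < oob.size(); ++k) {
        const int i = oob[k];
        int node = 0;
        while (t.feature[node] >= 0) {
          const int f = t.feature[node];
          const double xv = (f == g) ? X(perm[i], f) : X(i, f);
          node = (xv <= t.thr[node]) ? t.left[node] : t.right[node];
        }
        sum[i] += t.value[node];
        cnt[i] += 1;
      }
    }
    score.clear();
    label.clear();
    for (int i = 0; i < n; ++i)
      if (cnt[i] > 0) {
        score.push_back(sum[i] / cnt[i]);
        label.push_back(y[i]);
      }
    return auc_rank(score, label);
  };

  for (int i = 0; i < n; ++i) perm[i] = i;
  const double base = oob_auc(-1);

  NumericVector out(cols.size());
  for (int c = 0; c < cols.size(); ++c) {
    double acc = 0.0;
    for (int b = 0; b < B; ++b) {
      // Fisher-Yates shuffle via R's RNG for set.seed() reproducibility
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      acc += base - oob_auc(cols[c]);
    }
    double imp = acc / B;
    out[c] = imp > 0 ? imp : 0.0;
  }
  return out;
}

// Out-of-bag aggregated prediction: each row is predicted only by trees
// whose bootstrap sample excluded it. Rows in every bag (rare) fall back
// to the all-tree mean.
// [[Rcpp::export]]
NumericVector forest_predict_oob_cpp(List trees, List oob_rows,
                                     NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector sum(n), all_sum(n);
  IntegerVector cnt(n);
  for (int b = 0; b < B; ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["threshold"], value = tree["value"];
    IntegerVector oob = oob_rows[b];
    for (int k = 0; k < oob.size(); ++k) {
      const int i = oob[k];
      sum[i] += value[descend(feature, thr, left, right, X, i)];
      cnt[i] += 1;
    }
    for (int i = 0; i < n; ++i)
      all_sum[i] += value[descend(feature, thr, left, right, X, i)];
  }
  for (int i = 0; i < n; ++i)
    sum[i] = cnt[i] > 0 ? sum[i] / cnt[i] : all_sum[i] / B;
  return sum;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["threshold"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += value[descend(feature, thr, left, right, X, i)];
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
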