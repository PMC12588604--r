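// Minimal regression CART used as the kernel for the package's bagged
// (random forest) and boosted tree learners. Greedy variance-reduction
// splits; per-node random feature subsampling (mtry) drawn from R's RNG so
// everything is deterministic under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  double value;     // leaf prediction (node mean)
  int left, right;  // child indices, -1 for leaf
};

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, IntegerVector rows,
               int mtry, int min_node, int max_depth) {
  const int p = X.ncol();
  std::vector<Node> nodes;
  // work stack: (node index, depth, row set)
  struct Task { int node; int depth; std::vector<int> rows; };
  std::vector<Task> stack;
  {
    std::vector<int> r(rows.begin(), rows.end());
    nodes.push_back(Node{-1, 0.0, 0.0, -1, -1});
    stack.push_back(Task{0, 0, r});
  }
  std::vector<int> feat_idx(p);

  while (!stack.empty()) {
    Task t = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& r = t.rows;
    const int n = (int)r.size();
    double sum = 0.0, sum2 = 0.0;
    for (int i = 0; i < n; ++i) { double v = y[r[i]]; sum += v; sum2 += v * v; }
    const double mean = sum / n;
    Node& nd0 = nodes[t.node];
    nd0.value = mean;
    const double sse = sum2 - sum * sum / n;
    if (t.depth >= max_depth || n < 2 * min_node || sse <= 1e-12) continue;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < p; ++j) feat_idx[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feat_idx[j], feat_idx[k]);
    }

    int best_f = -1; double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double, double> > xv(n); // (x, y)
    for (int jj = 0; jj < m; ++jj) {
      const int f = feat_idx[jj];
      for (int i = 0; i < n; ++i) xv[i] = std::make_pair(X(r[i], f), y[r[i]]);
      std::sort(xv.begin(), xv.end());
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xv[i].second;
        if (xv[i].first == xv[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(r[i], best_f) <= best_thr) lrows.push_back(r[i]);
      else rrows.push_back(r[i]);
    }
    if (lrows.empty() || rrows.empty()) continue;

    int li = (int)nodes.size(), ri = li + 1;
    nodes.push_back(Node{-1, 0.0, 0.0, -1, -1});
    nodes.push_back(Node{-1, 0.0, 0.0, -1, -1});
    Node& nd = nodes[t.node];
    nd.feature = best_f; nd.threshold = best_thr;
    nd.left = li; nd.right = ri;
    stack.push_back(Task{li, t.depth + 1, std::move(lrows)});
    stack.push_back(Task{ri, t.depth + 1, std::move(rrows)});
  }

  const int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn), value(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature; threshold[i] = nodes[i].threshold;
    value[i] = nodes[i].value; left[i] = nodes[i].left; right[i] = nodes[i].right;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["value"] = value, _["left"] = left, _["right"] = right);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
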