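#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Tree node matrix layout (one row per node):
//   0 feature   1-based split feature, 0 for a leaf
//   1 threshold split point (midpoint between consecutive in-bag values)
//   2 left      1-based row of left child (x <= threshold), 0 for a leaf
//   3 right     1-based row of right child, 0 for a leaf
//   4 value     mean in-bag response in the node (leaf prediction)
//   5 depth     root = 0
//   6 n_node    number of in-bag rows in the node
static const int T_FEATURE = 0, T_THRESHOLD = 1, T_LEFT = 2, T_RIGHT = 3,
                 T_VALUE = 4, T_DEPTH = 5, T_NNODE = 6, T_NCOL = 7;

// uniform integer in [0, n) from R's RNG
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// first k of a Fisher-Yates shuffle of 0..n-1 (sample without replacement)
static void sample_without_replacement(int n, int k, std::vector<int> &out,
                                       std::vector<int> &pool) {
  pool.resize(n);
  std::iota(pool.begin(), pool.end(), 0);
  out.resize(k);
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(n - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct NodeRec {
  double v[T_NCOL];
};

struct BestSplit {
  int feature;       // 0-based, -1 if none
  double threshold;
  double reduction;  // decrease in pooled SSE; must be > 0 to split
};

// Exhaustive best split for one candidate feature on the rows in `idx`.
// Candidate thresholds are midpoints between consecutive distinct sorted
// values; criterion is the reduction in sum of squared deviations from the
// child means relative to the parent node.
static void best_split_for_feature(const NumericMatrix &X,
                                   const NumericVector &y,
                                   const std::vector<int> &idx, int f,
                                   double parent_sse,
                                   std::vector<std::pair<double, double>> &xy,
                                   BestSplit &best) {
  const int m = (int)idx.size();
  xy.resize(m);
  for (int i = 0; i < m; ++i) xy[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
  std::sort(xy.begin(), xy.end());
  if (xy.front().first == xy.back().first) return;  // constant feature

  double total = 0.0;
  for (int i = 0; i < m; ++i) total += xy[i].second;

  double suml = 0.0;
  for (int i = 0; i < m - 1; ++i) {
    suml += xy[i].second;
    if (xy[i].first == xy[i + 1].first) continue;
    const int nl = i + 1, nr = m - nl;
    const double sumr = total - suml;
    // SSE_parent - (SSE_l + SSE_r) = sum_l^2/nl + sum_r^2/nr - total^2/m
    const double reduction =
        suml * suml / nl + sumr * sumr / nr - total * total / m;
    // strict improvement; ties resolved by scan order (ascending feature
    // index outside, ascending threshold here), so first winner is kept
    if (reduction > best.reduction + 1e-12 &&
        reduction > 1e-12 * (parent_sse + 1.0)) {
      best.feature = f;
      best.threshold = (xy[i].first + xy[i + 1].first) / 2.0;
      best.reduction = reduction;
    }
  }
}

// Grow one CART regression tree on the rows `inbag` (0-based).
static NumericMatrix grow_tree(const NumericMatrix &X, const NumericVector &y,
                               const std::vector<int> &inbag, int mtry,
                               int min_node_size) {
  const int p = X.ncol();
  std::vector<NodeRec> nodes;
  // work stack: (node row, depth) plus per-node row lists held separately
  std::vector<std::vector<int>> node_rows;
  std::vector<int> open;  // indices into nodes/node_rows awaiting processing

  nodes.push_back(NodeRec());
  node_rows.push_back(inbag);
  nodes[0].v[T_DEPTH] = 0;
  open.push_back(0);

  std::vector<int> cand, pool;
  std::vector<std::pair<double, double>> xy;

  while (!open.empty()) {
    const int ni = open.back();
    open.pop_back();
    std::vector<int> rows;
    rows.swap(node_rows[ni]);
    const int m = (int)rows.size();

    double sum = 0.0, sumsq = 0.0;
    for (int i = 0; i < m; ++i) {
      sum += y[rows[i]];
      sumsq += y[rows[i]] * y[rows[i]];
    }
    const double mean = sum / m;
    const double sse = sumsq - sum * sum / m;

    NodeRec &nd = nodes[ni];
    nd.v[T_VALUE] = mean;
    nd.v[T_NNODE] = m;
    nd.v[T_FEATURE] = 0;
    nd.v[T_THRESHOLD] = NA_REAL;
    nd.v[T_LEFT] = 0;
    nd.v[T_RIGHT] = 0;

    if (m < min_node_size || sse <= 1e-12) continue;  // terminal

    sample_without_replacement(p, mtry, cand, pool);
    std::sort(cand.begin(), cand.end());
    BestSplit best;
    best.feature = -1;
    best.threshold = 0.0;
    best.reduction = 0.0;
    for (int c = 0; c < (int)cand.size(); ++c)
      best_split_for_feature(X, y, rows, cand[c], sse, xy, best);
    if (best.feature < 0) continue;  // no admissible split among candidates

    std::vector<int> left, right;
    left.reserve(m);
    right.reserve(m);
    for (int i = 0; i < m; ++i) {
      if (X(rows[i], best.feature) <= best.threshold)
        left.push_back(rows[i]);
      else
        right.push_back(rows[i]);
    }

    const int li = (int)nodes.size();
    const int ri = li + 1;
    nodes[ni].v[T_FEATURE] = best.feature + 1;
    nodes[ni].v[T_THRESHOLD] = best.threshold;
    nodes[ni].v[T_LEFT] = li + 1;
    nodes[ni].v[T_RIGHT] = ri + 1;
    const double child_depth = nodes[ni].v[T_DEPTH] + 1;

    nodes.push_back(NodeRec());
    nodes.push_back(NodeRec());
    nodes[li].v[T_DEPTH] = child_depth;
    nodes[ri].v[T_DEPTH] = child_depth;
    node_rows.resize(nodes.size());
    node_rows[li].swap(left);
    node_rows[ri].swap(right);
    open.push_back(li);
    open.push_back(ri);
  }

  NumericMatrix out((int)nodes.size(), T_NCOL);
  for (int i = 0; i < (int)nodes.size(); ++i)
    for (int j = 0; j < T_NCOL; ++j) out(i, j) = nodes[i].v[j];
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "depth", "n_node");
  return out;
}

// Predict one row; when sub_feature >= 0 (0-based) the value of that
// feature is replaced by sub_value during the walk.
static inline double predict_row(const NumericMatrix &tree,
                                 const NumericMatrix &X, int row,
                                 int sub_feature, double sub_value) {
  int node = 0;
  while (tree(node, T_FEATURE) > 0) {
    const int f = (int)tree(node, T_FEATURE) - 1;
    const double x = (f == sub_feature) ? sub_value : X(row, f);
    node = (x <= tree(node, T_THRESHOLD)) ? (int)tree(node, T_LEFT) - 1
                                          : (int)tree(node, T_RIGHT) - 1;
  }
  return tree(node, T_VALUE);
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
                     int min_node_size, double subsample_fraction) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be between 1 and ncol(X)");
  if (n < 2) stop("need at least 2 observations");
  const int k = (int)std::lround(subsample_fraction * n);
  if (k < 1 || k > n) stop("subsample_fraction gives an empty or full sample");

  List trees(ntree), inbag(ntree), oob(ntree);
  std::vector<int> draw, pool;
  std::vector<char> flag(n);
  for (int t = 0; t < ntree; ++t) {
    sample_without_replacement(n, k, draw, pool);
    std::sort(draw.begin(), draw.end());
    std::fill(flag.begin(), flag.end(), 0);
    for (int i = 0; i < k; ++i) flag[draw[i]] = 1;
    IntegerVector ib(k), ob(n - k);
    for (int i = 0; i < k; ++i) ib[i] = draw[i] + 1;
    for (int i = 0, j = 0; i < n; ++i)
      if (!flag[i]) ob[j++] = i + 1;
    trees[t] = grow_tree(X, y, draw, mtry, min_node_size);
    inbag[t] = ib;
    oob[t] = ob;
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag, _["oob"] = oob);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(NumericMatrix tree, NumericMatrix X,
                               IntegerVector rows) {
  NumericVector out(rows.size());
  for (int i = 0; i < rows.size(); ++i)
    out[i] = predict_row(tree, X, rows[i] - 1, -1, 0.0);
  return out;
}

// Permutation importance. For each tree and predictor: permute the
// predictor's values among that tree's OOB rows (within strata when a
// conditioning set is supplied), recompute the OOB MSE through the tree,
// and record permuted-MSE minus original-MSE.
//
// cond_sets: list of p integer vectors (1-based conditioning predictors;
//   empty vector = unconditional permutation for that predictor).
// strata_mode: 0 = strata from the tree's own split points on the
//   conditioning predictors; 1 = cross-classified global quantile bins
//   (qbins, n x p, 1-based bin ids).
// Predictors a tree never splits on are skipped: permuting them cannot
// change any prediction, so their difference is exactly 0.
// [[Rcpp::export]]
NumericMatrix cpp_vim(List trees, List oob, NumericMatrix X, NumericVector y,
                      List cond_sets, int strata_mode,
                      Rcpp::Nullable<IntegerMatrix> qbins, int nperm) {
  const int ntree = trees.size(), p = X.ncol();
  NumericMatrix diffs(ntree, p);
  IntegerMatrix qb;
  if (strata_mode == 1) {
    if (qbins.isNull()) stop("quantile_bins strata require bin ids");
    qb = qbins.get();
  }

  std::vector<double> thresholds;
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    IntegerVector ob = oob[t];
    const int m = ob.size();
    if (m == 0) continue;

    std::vector<char> used(p, 0);
    for (int i = 0; i < tree.nrow(); ++i)
      if (tree(i, T_FEATURE) > 0) used[(int)tree(i, T_FEATURE) - 1] = 1;

    double mse0 = 0.0;
    for (int i = 0; i < m; ++i) {
      const double e = y[ob[i] - 1] - predict_row(tree, X, ob[i] - 1, -1, 0.0);
      mse0 += e * e;
    }
    mse0 /= m;

    std::vector<long long> key(m);
    std::vector<int> order(m), grp_of(m);
    std::vector<double> vals(m), pv(m);

    for (int j = 0; j < p; ++j) {
      if (!used[j]) { diffs(t, j) = 0.0; continue; }

      // stratum key per OOB row from the conditioning set
      IntegerVector cs = cond_sets[j];
      std::fill(key.begin(), key.end(), 0LL);
      for (int ci = 0; ci < cs.size(); ++ci) {
        const int c = cs[ci] - 1;
        if (strata_mode == 1) {
          int nb = 0;
          for (int i = 0; i < m; ++i) nb = std::max(nb, qb(ob[i] - 1, c));
          for (int i = 0; i < m; ++i)
            key[i] = key[i] * (nb + 1) + qb(ob[i] - 1, c);
        } else {
          thresholds.clear();
          for (int r = 0; r < tree.nrow(); ++r)
            if ((int)tree(r, T_FEATURE) - 1 == c)
              thresholds.push_back(tree(r, T_THRESHOLD));
          if (thresholds.empty()) continue;  // no refinement from c
          std::sort(thresholds.begin(), thresholds.end());
          thresholds.erase(
              std::unique(thresholds.begin(), thresholds.end()),
              thresholds.end());
          const int nb = (int)thresholds.size() + 1;
          for (int i = 0; i < m; ++i) {
            const int bin =
                (int)(std::upper_bound(thresholds.begin(), thresholds.end(),
                                       X(ob[i] - 1, c)) -
                      thresholds.begin());
            key[i] = key[i] * nb + bin;
          }
        }
      }

      // group OOB positions by stratum (stable order within stratum)
      std::iota(order.begin(), order.end(), 0);
      std::stable_sort(order.begin(), order.end(),
                       [&](int a, int b) { return key[a] < key[b]; });

      for (int i = 0; i < m; ++i) vals[i] = X(ob[i] - 1, j);
      double dsum = 0.0;
      for (int rep = 0; rep < nperm; ++rep) {
        // Fisher-Yates within each stratum segment
        for (int i = 0; i < m; ++i) pv[i] = vals[i];
        int s = 0;
        while (s < m) {
          int e = s;
          while (e + 1 < m && key[order[e + 1]] == key[order[s]]) ++e;
          for (int i = e; i > s; --i) {
            const int r = s + runif_int(i - s + 1);
            std::swap(pv[order[i]], pv[order[r]]);
          }
          s = e + 1;
        }
        double mse1 = 0.0;
        for (int i = 0; i < m; ++i) {
          const double e2 =
              y[ob[i] - 1] - predict_row(tree, X, ob[i] - 1, j, pv[i]);
          mse1 += e2 * e2;
        }
        dsum += mse1 / m - mse0;
      }
      diffs(t, j) = dsum / nperm;
    }
  }
  return diffs;
}
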