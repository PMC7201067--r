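// Decision-tree kernels shared by the Monte Carlo feature selection trees
// (entropy / information-gain splits grown to purity) and the PART partial
// trees (gain-ratio splits searched one node at a time from R).
//
// All entropies and gains are in bits. Class labels are 0-based integers.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double xlog2(double p) {
  return (p > 0.0) ? p * std::log2(p) : 0.0;
}

static double entropy_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double h = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    h -= xlog2(static_cast<double>(cnt[k]) / n);
  }
  return h;
}

struct Split {
  int feature;      // 0-based column, -1 if none found
  double threshold; // midpoint between adjacent distinct sorted values
  double gain;      // information gain in bits
  double ratio;     // gain ratio (gain / split info)
  int n_left;
  int n_right;
};

// Search the best binary split over the given rows. criterion = 0 picks the
// split maximizing information gain, criterion = 1 maximizes gain ratio
// (among splits with positive gain). Both children must hold >= min_leaf
// rows. Ties break to the lower column index, then the lower threshold.
static Split best_split(const NumericMatrix &X, const IntegerVector &y,
                        const std::vector<int> &rows, int nclass,
                        int min_leaf, int criterion) {
  const int n = rows.size();
  Split best = {-1, 0.0, 0.0, 0.0, 0, 0};
  if (n < 2 * min_leaf) return best;

  std::vector<int> total(nclass, 0);
  for (int i = 0; i < n; ++i) total[y[rows[i]]]++;
  const double h_parent = entropy_counts(total, n);
  if (h_parent <= 0.0) return best;

  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> left(nclass), right(nclass);
  // incremental entropy bookkeeping: S = sum over classes of c*log2(c)
  double s_total = 0.0;
  for (int k = 0; k < nclass; ++k) {
    if (total[k] > 0) s_total += total[k] * std::log2((double)total[k]);
  }

  for (int j = 0; j < X.ncol(); ++j) {
    for (int i = 0; i < n; ++i) {
      vals[i] = std::make_pair(X(rows[i], j), y[rows[i]]);
    }
    std::sort(vals.begin(), vals.end());
    std::fill(left.begin(), left.end(), 0);
    std::copy(total.begin(), total.end(), right.begin());
    double sl = 0.0, sr = s_total;
    for (int i = 0; i < n - 1; ++i) {
      const int c = vals[i].second;
      const int cl = left[c], cr = right[c];
      sl += (cl + 1) * std::log2((double)(cl + 1)) -
            (cl > 0 ? cl * std::log2((double)cl) : 0.0);
      sr += (cr > 1 ? (cr - 1) * std::log2((double)(cr - 1)) : 0.0) -
            cr * std::log2((double)cr);
      left[c] = cl + 1;
      right[c] = cr - 1;
      if (vals[i].first == vals[i + 1].first) continue;  // not a boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double hl = std::log2((double)nl) - sl / nl;
      const double hr = std::log2((double)nr) - sr / nr;
      const double pl = static_cast<double>(nl) / n;
      const double gain = h_parent - pl * hl - (1.0 - pl) * hr;
      if (gain <= 1e-12) continue;
      double score = gain;
      double ratio = gain;
      if (criterion == 1) {
        const double si = -xlog2(pl) - xlog2(1.0 - pl);
        if (si <= 0.0) continue;
        ratio = gain / si;
        score = ratio;
      }
      const double best_score = (criterion == 1) ? best.ratio : best.gain;
      if (best.feature < 0 || score > best_score + 1e-12) {
        best.feature = j;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        best.gain = gain;
        best.ratio = ratio;
        best.n_left = nl;
        best.n_right = nr;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, IntegerVector rows,
                    int nclass, int min_leaf, int criterion) {
  std::vector<int> rr(rows.begin(), rows.end());
  Split s = best_split(X, y, rr, nclass, min_leaf, criterion);
  return List::create(_["feature"] = s.feature + 1,  // 1-based, 0 = none
                      _["threshold"] = s.threshold,
                      _["gain"] = s.gain,
                      _["gain_ratio"] = s.ratio,
                      _["n_left"] = s.n_left,
                      _["n_right"] = s.n_right);
}

// Grow a binary entropy tree to purity (or min_leaf exhaustion) over the
// given rows. Returns a flat node table; children reference 1-based node
// ids, 0 marks a leaf side.
// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                   int nclass, int min_leaf) {
  std::vector<int> feature, n_node, left_child, right_child, pred;
  std::vector<double> threshold, gain;

  struct Task { std::vector<int> rows; int slot; };
  std::vector<Task> stack;
  {
    Task root;
    root.rows.assign(rows.begin(), rows.end());
    root.slot = -1;
    stack.push_back(root);
  }

  while (!stack.empty()) {
    Task task = stack.back();
    stack.pop_back();
    const int id = feature.size();  // 0-based id of the node we create
    if (task.slot >= 0) {
      // patch parent's child pointer (slot encodes parent*2 + side)
      const int parent = task.slot >> 1;
      if ((task.slot & 1) == 0) left_child[parent] = id + 1;
      else right_child[parent] = id + 1;
    }

    const int n = task.rows.size();
    std::vector<int> cnt(nclass, 0);
    for (int i = 0; i < n; ++i) cnt[y[task.rows[i]]]++;
    int maj = 0;
    for (int k = 1; k < nclass; ++k) if (cnt[k] > cnt[maj]) maj = k;

    Split s = best_split(X, y, task.rows, nclass, min_leaf, 0);

    feature.push_back(s.feature + 1);
    threshold.push_back(s.threshold);
    gain.push_back(s.feature >= 0 ? s.gain : 0.0);
    n_node.push_back(n);
    left_child.push_back(0);
    right_child.push_back(0);
    pred.push_back(maj);

    if (s.feature >= 0) {
      Task lt, rt;
      lt.slot = id * 2;
      rt.slot = id * 2 + 1;
      for (int i = 0; i < n; ++i) {
        if (X(task.rows[i], s.feature) <= s.threshold) {
          lt.rows.push_back(task.rows[i]);
        } else {
          rt.rows.push_back(task.rows[i]);
        }
      }
      // push right first so the left child is materialized first
      stack.push_back(rt);
      stack.push_back(lt);
    }
  }

  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["gain"] = wrap(gain),
                      _["n_node"] = wrap(n_node),
                      _["left"] = wrap(left_child),
                      _["right"] = wrap(right_child),
                      _["pred"] = wrap(pred));
}

// ---- PART partial-tree construction ------------------------------------
//
// Grows a C4.5-style tree only partially: the unexpanded subset with the
// lowest class entropy is always expanded first; once a fully-expanded
// subtree resists pessimistic pruning, growth stops everywhere and the
// single best rule (path to the real leaf with the largest coverage) is
// extracted. Subsets left unexpanded are never rule candidates.

static double pessimistic_errors(int n, int e, double cf) {
  if (n == 0) return 0.0;
  if (e >= n) return n;
  return n * R::qbeta(1.0 - cf, e + 1.0, static_cast<double>(n - e), 1, 0);
}

struct PartCtx {
  const NumericMatrix *X;
  const IntegerVector *y;
  int nclass;
  int min_leaf;
  double cf;
  bool stop;
  int counter;        // node-entry (expansion) order
  // best real leaf so far
  int best_cov;
  int best_order;
  std::vector<int> best_rows;
  int best_pred;
  int best_err;
  std::vector<int> cond_feature;   // path to best leaf, filled on unwind
  std::vector<double> cond_thr;
  std::vector<int> cond_leq;       // 1 = "<=", 0 = ">"
};

static double subset_entropy(const IntegerVector &y,
                             const std::vector<int> &rows, int nclass) {
  std::vector<int> cnt(nclass, 0);
  for (size_t i = 0; i < rows.size(); ++i) cnt[y[rows[i]]]++;
  return entropy_counts(cnt, rows.size());
}

// Register a real leaf as rule candidate. Nodes are visited depth-first,
// so at any unwind point every previously registered leaf has a smaller
// entry order; a later leaf only wins with strictly larger coverage,
// which realizes the "largest coverage, ties to the first reached" rule.
// `force` is used when a pruned node swallows the subtree holding the
// current best leaf (that leaf no longer exists; the pruned node covers
// a strict superset of it).
static void register_leaf(PartCtx &ctx, const std::vector<int> &rows,
                          int maj, int err, int order, bool force) {
  const int n = rows.size();
  if (force || ctx.best_cov < 0 || n > ctx.best_cov) {
    ctx.best_cov = n;
    ctx.best_order = order;
    ctx.best_rows = rows;
    ctx.best_pred = maj;
    ctx.best_err = err;
    ctx.cond_feature.clear();
    ctx.cond_thr.clear();
    ctx.cond_leq.clear();
  }
}

// Returns true when this subtree collapsed to a real leaf.
static bool part_expand(PartCtx &ctx, const std::vector<int> &rows) {
  const int n = rows.size();
  std::vector<int> cnt(ctx.nclass, 0);
  for (int i = 0; i < n; ++i) cnt[(*ctx.y)[rows[i]]]++;
  int maj = 0;
  for (int k = 1; k < ctx.nclass; ++k) if (cnt[k] > cnt[maj]) maj = k;

  const int my_order = ++ctx.counter;

  Split s = {-1, 0.0, 0.0, 0.0, 0, 0};
  bool leafify = (cnt[maj] == n) || (n < 2 * ctx.min_leaf);
  if (!leafify) {
    s = best_split(*ctx.X, *ctx.y, rows, ctx.nclass, ctx.min_leaf, 1);
    leafify = (s.feature < 0);
  }
  if (leafify) {
    register_leaf(ctx, rows, maj, n - cnt[maj], my_order, false);
    return true;
  }

  std::vector<int> kids[2];
  for (int i = 0; i < n; ++i) {
    if ((*ctx.X)(rows[i], s.feature) <= s.threshold) kids[0].push_back(rows[i]);
    else kids[1].push_back(rows[i]);
  }
  // expand the lower-entropy subset first (ties: the "<=" side)
  const int first =
    (subset_entropy(*ctx.y, kids[1], ctx.nclass) <
     subset_entropy(*ctx.y, kids[0], ctx.nclass)) ? 1 : 0;

  bool all_leaves = true;
  int child_start[2] = {0, 0}, child_end[2] = {0, 0};
  for (int step = 0; step < 2; ++step) {
    const int side = (step == 0) ? first : 1 - first;
    child_start[side] = ctx.counter + 1;
    if (ctx.stop) {
      all_leaves = false;   // unexpanded subset: not a leaf, not a candidate
    } else {
      if (!part_expand(ctx, kids[side])) all_leaves = false;
    }
    child_end[side] = ctx.counter;
  }

  if (!ctx.stop && all_leaves) {
    // both children are real leaves: C4.5 subtree-replacement check
    double sub_err = 0.0;
    for (int side = 0; side < 2; ++side) {
      std::vector<int> c2(ctx.nclass, 0);
      for (size_t i = 0; i < kids[side].size(); ++i)
        c2[(*ctx.y)[kids[side][i]]]++;
      int m2 = 0;
      for (int k = 1; k < ctx.nclass; ++k) if (c2[k] > c2[m2]) m2 = k;
      sub_err += pessimistic_errors(kids[side].size(),
                                    kids[side].size() - c2[m2], ctx.cf);
    }
    const double node_err = pessimistic_errors(n, n - cnt[maj], ctx.cf);
    if (node_err <= sub_err + 1e-9) {
      // replaced by a leaf; descendants (incl. a best leaf inside) vanish
      const bool best_inside = (ctx.best_order >= my_order);
      register_leaf(ctx, rows, maj, n - cnt[maj], my_order, best_inside);
      return true;
    }
    ctx.stop = true;  // subtree kept: the partial tree is finished
  }

  // internal node: while unwinding, prepend our condition if the best
  // leaf lies in one of our (expanded) children
  for (int side = 0; side < 2; ++side) {
    if (ctx.best_order >= child_start[side] &&
        ctx.best_order <= child_end[side] &&
        child_start[side] <= child_end[side]) {
      ctx.cond_feature.push_back(s.feature);
      ctx.cond_thr.push_back(s.threshold);
      ctx.cond_leq.push_back(side == 0 ? 1 : 0);
      break;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_partial_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                      int nclass, int min_leaf, double cf) {
  PartCtx ctx;
  ctx.X = &X;
  ctx.y = &y;
  ctx.nclass = nclass;
  ctx.min_leaf = min_leaf;
  ctx.cf = cf;
  ctx.stop = false;
  ctx.counter = 0;
  ctx.best_cov = -1.0;
  ctx.best_order = -1;
  ctx.best_pred = 0;
  ctx.best_err = 0;

  ctx.best_pred = 0;
  ctx.best_err = 0;
  std::vector<int> rr(rows.begin(), rows.end());
  part_expand(ctx, rr);

  // conditions were collected leaf -> root; reverse to root -> leaf
  std::reverse(ctx.cond_feature.begin(), ctx.cond_feature.end());
  std::reverse(ctx.cond_thr.begin(), ctx.cond_thr.end());
  std::reverse(ctx.cond_leq.begin(), ctx.cond_leq.end());

  IntegerVector feat(ctx.cond_feature.begin(), ctx.cond_feature.end());
  for (int i = 0; i < feat.size(); ++i) feat[i] += 1;  // 1-based columns
  IntegerVector matched(ctx.best_rows.begin(), ctx.best_rows.end());
  for (int i = 0; i < matched.size(); ++i) matched[i] += 1;

  return List::create(_["feature"] = feat,
                      _["threshold"] = wrap(ctx.cond_thr),
                      _["leq"] = wrap(ctx.cond_leq),
                      _["pred"] = ctx.best_pred,
                      _["matched"] = matched,
                      _["coverage"] = static_cast<int>(ctx.best_cov),
                      _["correct"] = static_cast<int>(ctx.best_cov) - ctx.best_err);
}

// Predict 0-based classes for new rows with a cpp_grow_tree node table.
// [[Rcpp::export]]
IntegerVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector pred, NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] > 0) {
      if (X(i, feature[node] - 1) <= threshold[node]) {
        if (left[node] == 0) break;
        node = left[node] - 1;
      } else {
        if (right[node] == 0) break;
        node = right[node] - 1;
      }
    }
    out[i] = pred[node];
  }
  return out;
}
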