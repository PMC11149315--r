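// Compiled learners and distance kernels.
//
// Nothing here owns a random seed: every stochastic routine draws from R's
// RNG stream (unif_rand), so set.seed() on the R side makes results
// reproducible and schedule-invariant.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <stack>
#include <vector>

using namespace Rcpp;

// uniform integer in [0, n) from R's RNG; guard against unif_rand() == 1-eps
static inline int rand_below(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// in-place Fisher-Yates using R's RNG
static void shuffle_idx(std::vector<int>& v) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = rand_below(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---------------------------------------------------------------------------
// Random-forest classifier.
//
// CART with Gini impurity, grown to purity, mtry features per node.
// Bootstrap resampling is encoded as per-sample integer weights (all copies
// of a sample share every feature value, so they always travel together and
// only weight the class counts). Per-feature sample orders are presorted
// once per training set and maintained through splits by stable partition,
// so no per-node sorting is ever needed: a node of m samples costs
// O(p * m) to split.
// ---------------------------------------------------------------------------

struct Tree {
  std::vector<int> feat;      // split feature, -1 for leaf
  std::vector<double> thr;    // go left if x <= thr
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf class
};

struct NodeRange { int node, start, end; };

static Tree grow_class_tree(const std::vector<double>& X,  // col-major n x p
                            int n, int p, const std::vector<int>& y,
                            int nclass, const std::vector<int>& w,
                            int mtry,
                            const std::vector<std::vector<int>>& ord) {
  Tree tr;
  auto new_node = [&]() {
    tr.feat.push_back(-1); tr.thr.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0);
    return static_cast<int>(tr.feat.size()) - 1;
  };
  new_node();

  // per-feature lists of in-bag samples, each in ascending feature order;
  // every node owns the same index range in all p lists
  std::vector<std::vector<int>> L(p);
  for (int f = 0; f < p; ++f) {
    L[f].reserve(n);
    for (int idx : ord[f]) if (w[idx] > 0) L[f].push_back(idx);
  }
  const int nb = static_cast<int>(L[0].size());

  std::vector<char> side(n);
  std::vector<int> tmp(nb);
  std::vector<int> feats(p), cnt(nclass), lcnt(nclass);
  std::stack<NodeRange> todo;
  todo.push({0, 0, nb});

  while (!todo.empty()) {
    NodeRange t = todo.top(); todo.pop();
    std::fill(cnt.begin(), cnt.end(), 0);
    int tw = 0;
    for (int i = t.start; i < t.end; ++i) {
      const int id = L[0][i];
      cnt[y[id]] += w[id];
      tw += w[id];
    }
    int maj = 0;
    for (int c = 1; c < nclass; ++c) if (cnt[c] > cnt[maj]) maj = c;
    tr.pred[t.node] = maj;
    if (tw < 2 || cnt[maj] == tw) continue;  // pure or single sample

    for (int j = 0; j < p; ++j) feats[j] = j;
    int best_f = -1; double best_thr = 0.0, best_score = -1.0;
    for (int m = 0; m < mtry; ++m) {
      int pick = m + rand_below(p - m);
      std::swap(feats[m], feats[pick]);
      const int f = feats[m];
      const double* col = X.data() + static_cast<size_t>(f) * n;
      const int* lst = L[f].data();
      std::fill(lcnt.begin(), lcnt.end(), 0);
      int lw = 0;
      double prev = 0.0;
      for (int i = t.start; i < t.end; ++i) {
        const int id = lst[i];
        const double v = col[id];
        if (lw > 0 && v > prev) {
          double sl = 0.0, sr = 0.0;
          for (int c = 0; c < nclass; ++c) {
            const double lc = lcnt[c];
            const double rc = cnt[c] - lcnt[c];
            sl += lc * lc; sr += rc * rc;
          }
          const double score = sl / lw + sr / (tw - lw);
          if (score > best_score) {
            best_score = score; best_f = f;
            best_thr = prev + (v - prev) / 2.0;
          }
        }
        lcnt[y[id]] += w[id];
        lw += w[id];
        prev = v;
      }
    }
    if (best_f < 0) continue;  // all candidate features constant here

    const double* col = X.data() + static_cast<size_t>(best_f) * n;
    int nl = 0;
    for (int i = t.start; i < t.end; ++i) {
      const int id = L[0][i];
      side[id] = (col[id] <= best_thr);
      nl += side[id];
    }
    if (nl == 0 || nl == t.end - t.start) continue;
    for (int f = 0; f < p; ++f) {
      int* lst = L[f].data();
      int out = t.start, ntmp = 0;
      for (int i = t.start; i < t.end; ++i) {
        const int id = lst[i];
        if (side[id]) lst[out++] = id; else tmp[ntmp++] = id;
      }
      std::copy(tmp.begin(), tmp.begin() + ntmp, lst + out);
    }
    const int lid = new_node();
    const int rid = new_node();
    tr.feat[t.node] = best_f; tr.thr[t.node] = best_thr;
    tr.left[t.node] = lid; tr.right[t.node] = rid;
    todo.push({lid, t.start, t.start + nl});
    todo.push({rid, t.start + nl, t.end});
  }
  return tr;
}

static int predict_tree(const Tree& tr, const double* row_major_x, int p) {
  (void)p;
  int node = 0;
  while (tr.feat[node] >= 0)
    node = (row_major_x[tr.feat[node]] <= tr.thr[node]) ? tr.left[node]
                                                        : tr.right[node];
  return tr.pred[node];
}

// Random-forest classifier: train ntree bootstrap trees on (Xtr, ytr) and
// return majority-vote predictions for Xte (ties -> lowest class id).
// [[Rcpp::export]]
IntegerVector cpp_rf_classify(NumericMatrix Xtr, IntegerVector ytr, int nclass,
                              NumericMatrix Xte, int ntree, int mtry) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> X(Xtr.begin(), Xtr.end());  // col-major copy
  std::vector<int> y(ytr.begin(), ytr.end());

  // presort every feature once; shared by all trees
  std::vector<std::vector<int>> ord(p);
  for (int f = 0; f < p; ++f) {
    ord[f].resize(n);
    for (int i = 0; i < n; ++i) ord[f][i] = i;
    const double* col = X.data() + static_cast<size_t>(f) * n;
    std::stable_sort(ord[f].begin(), ord[f].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  // row-major copy of the test matrix for cheap traversal
  std::vector<double> te(static_cast<size_t>(nte) * p);
  for (int i = 0; i < nte; ++i)
    for (int f = 0; f < p; ++f) te[static_cast<size_t>(i) * p + f] = Xte(i, f);

  std::vector<std::vector<int>> votes(nte, std::vector<int>(nclass, 0));
  std::vector<int> w(n);
  for (int b = 0; b < ntree; ++b) {
    std::fill(w.begin(), w.end(), 0);
    for (int i = 0; i < n; ++i) w[rand_below(n)]++;
    Tree tr = grow_class_tree(X, n, p, y, nclass, w, mtry, ord);
    for (int i = 0; i < nte; ++i)
      votes[i][predict_tree(tr, te.data() + static_cast<size_t>(i) * p, p)]++;
  }
  IntegerVector out(nte);
  for (int i = 0; i < nte; ++i) {
    int best = 0;
    for (int c = 1; c < nclass; ++c) if (votes[i][c] > votes[i][best]) best = c;
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random-forest regressor, used only for the 5-feature weight regression:
// recursive variance-reduction CART with per-node sorting (cheap at that
// width), reporting impurity-decrease feature importances.
// ---------------------------------------------------------------------------

struct NodeTask { int start, end; };

static void grow_reg_tree(const NumericMatrix& X, const NumericVector& y,
                          std::vector<int>& idx, int mtry,
                          std::vector<double>& imp) {
  const int p = X.ncol();
  const int ntot = static_cast<int>(idx.size());
  std::stack<NodeTask> todo;
  todo.push({0, ntot});
  std::vector<int> feats(p);
  std::vector<std::pair<double,int>> buf;

  while (!todo.empty()) {
    NodeTask t = todo.top(); todo.pop();
    const int n = t.end - t.start;
    if (n < 2) continue;
    double s = 0.0, ss = 0.0;
    for (int i = t.start; i < t.end; ++i) { double v = y[idx[i]]; s += v; ss += v * v; }
    double node_var = ss / n - (s / n) * (s / n);
    if (node_var <= 0.0) continue;

    for (int j = 0; j < p; ++j) feats[j] = j;
    int best_f = -1; double best_thr = 0.0, best_score = -1.0;
    double best_ls = 0.0, best_lss = 0.0; int best_nl = 0;
    for (int m = 0; m < mtry; ++m) {
      int pick = m + rand_below(p - m);
      std::swap(feats[m], feats[pick]);
      const int f = feats[m];
      buf.clear();
      for (int i = t.start; i < t.end; ++i) buf.push_back({X(idx[i], f), idx[i]});
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      double ls = 0.0, lss = 0.0;
      for (int i = 1; i < n; ++i) {
        double v = y[buf[i - 1].second];
        ls += v; lss += v * v;
        if (buf[i].first <= buf[i - 1].first) continue;
        double score = ls * ls / i + (s - ls) * (s - ls) / (n - i);
        if (score > best_score) {
          best_score = score; best_f = f;
          best_thr = buf[i - 1].first + (buf[i].first - buf[i - 1].first) / 2.0;
          best_ls = ls; best_lss = lss; best_nl = i;
        }
      }
    }
    if (best_f < 0) continue;

    // weighted impurity decrease, scikit-learn convention
    double lvar = best_lss / best_nl - (best_ls / best_nl) * (best_ls / best_nl);
    int nr = n - best_nl;
    double rs = s - best_ls, rss = ss - best_lss;
    double rvar = rss / nr - (rs / nr) * (rs / nr);
    if (lvar < 0) lvar = 0;
    if (rvar < 0) rvar = 0;
    double decrease = (static_cast<double>(n) / ntot) *
      (node_var - (static_cast<double>(best_nl) / n) * lvar
                - (static_cast<double>(nr) / n) * rvar);
    if (decrease > 0) imp[best_f] += decrease;

    int bf = best_f; double bt = best_thr;
    int* base = idx.data();
    int* mid = std::stable_partition(base + t.start, base + t.end,
      [&X, bf, bt](int r) { return X(r, bf) <= bt; });
    int nmid = static_cast<int>(mid - base);
    if (nmid == t.start || nmid == t.end) continue;
    todo.push({t.start, nmid});
    todo.push({nmid, t.end});
  }
}

// Per-tree impurity-decrease importances normalised to sum 1, averaged
// over ntree bootstrap trees (then renormalised).
// [[Rcpp::export]]
NumericVector cpp_rf_regress_importance(NumericMatrix X, NumericVector y,
                                        int ntree, int mtry) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector avg(p);
  std::vector<int> boot(n);
  std::vector<double> imp(p);
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) boot[i] = rand_below(n);
    std::fill(imp.begin(), imp.end(), 0.0);
    grow_reg_tree(X, y, boot, mtry, imp);
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += imp[j];
    if (tot > 0) for (int j = 0; j < p; ++j) avg[j] += imp[j] / tot;
  }
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += avg[j];
  if (tot > 0) for (int j = 0; j < p; ++j) avg[j] /= tot;
  return avg;
}

// ---------------------------------------------------------------------------
// Linear hinge-loss classifier trained by stochastic gradient descent,
// one-vs-rest, eta_t = 1 / (alpha * (t0 + t)) (the "optimal" schedule of the
// paper's ecosystem); bias unregularised. X must already be standardised.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sgd_hinge_fit(NumericMatrix X, IntegerVector y, int nclass,
                                int epochs, double alpha) {
  const int n = X.nrow(), p = X.ncol();
  // row-major copy for per-sample locality
  std::vector<double> xr(static_cast<size_t>(n) * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xr[static_cast<size_t>(i) * p + j] = X(i, j);

  std::vector<double> W(static_cast<size_t>(p + 1) * nclass, 0.0);
  const double typw = std::sqrt(1.0 / std::sqrt(alpha));
  const double eta0 = typw;        // hinge derivative bound = 1
  const double t0 = 1.0 / (eta0 * alpha);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  long t = 0;
  for (int e = 0; e < epochs; ++e) {
    shuffle_idx(ord);
    for (int ii = 0; ii < n; ++ii) {
      const int i = ord[ii];
      const double* x = xr.data() + static_cast<size_t>(i) * p;
      ++t;
      const double eta = 1.0 / (alpha * (t0 + t));
      const double shrink = 1.0 - eta * alpha;
      for (int c = 0; c < nclass; ++c) {
        double* wc = W.data() + static_cast<size_t>(c) * (p + 1);
        const double s = (y[i] == c) ? 1.0 : -1.0;
        double m = wc[p];
        for (int j = 0; j < p; ++j) m += wc[j] * x[j];
        m *= s;
        if (m < 1.0) {
          const double step = eta * s;
          for (int j = 0; j < p; ++j) wc[j] = wc[j] * shrink + step * x[j];
          wc[p] += step;
        } else {
          for (int j = 0; j < p; ++j) wc[j] *= shrink;
        }
      }
    }
  }
  NumericMatrix out(p + 1, nclass);
  for (int c = 0; c < nclass; ++c)
    for (int j = 0; j <= p; ++j)
      out(j, c) = W[static_cast<size_t>(c) * (p + 1) + j];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_linear_predict(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), p = X.ncol(), k = W.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0; double bestv = -HUGE_VAL;
    for (int c = 0; c < k; ++c) {
      double v = W(p, c);
      for (int j = 0; j < p; ++j) v += W(j, c) * X(i, j);
      if (v > bestv) { bestv = v; best = c; }
    }
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Class-overlap support: for every sample, how many of its k nearest
// neighbours (Euclidean, self excluded, distance ties broken by ascending
// row index) carry a different label.
// ---------------------------------------------------------------------------

static std::vector<double> row_major_copy(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xr(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xr[static_cast<size_t>(i) * p + j] = X(i, j);
  return xr;
}

static inline double sqdist(const double* a, const double* b, int p) {
  double s = 0.0;
  for (int f = 0; f < p; ++f) {
    const double d = a[f] - b[f];
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
IntegerVector cpp_knn_foreign_counts(NumericMatrix X, IntegerVector cls, int k) {
  const int n = X.nrow(), p = X.ncol();
  if (k >= n) stop("k must be smaller than the number of samples");
  std::vector<double> xr = row_major_copy(X);
  IntegerVector out(n);
  std::vector<std::pair<double,int>> d(n - 1);
  for (int i = 0; i < n; ++i) {
    const double* xi = xr.data() + static_cast<size_t>(i) * p;
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d[m++] = {sqdist(xi, xr.data() + static_cast<size_t>(j) * p, p), j};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    int foreign = 0;
    for (int q = 0; q < k; ++q)
      if (cls[d[q].second] != cls[i]) ++foreign;
    out[i] = foreign;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Silhouette samples: s_i = (b_i - a_i) / max(a_i, b_i) with a = mean
// within-cluster distance (self excluded), b = mean distance to the nearest
// other cluster; singletons and degenerate max(a,b) = 0 give s = 0.
// cl must be 0-based cluster ids.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_silhouette_samples(NumericMatrix X, IntegerVector cl, int ncl) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xr = row_major_copy(X);
  std::vector<int> sz(ncl, 0);
  for (int i = 0; i < n; ++i) sz[cl[i]]++;
  NumericVector out(n);
  std::vector<double> sums(ncl);
  for (int i = 0; i < n; ++i) {
    std::fill(sums.begin(), sums.end(), 0.0);
    const double* xi = xr.data() + static_cast<size_t>(i) * p;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      sums[cl[j]] += std::sqrt(sqdist(xi, xr.data() + static_cast<size_t>(j) * p, p));
    }
    const int own = cl[i];
    if (sz[own] <= 1) { out[i] = 0.0; continue; }
    double a = sums[own] / (sz[own] - 1);
    double b = HUGE_VAL;
    for (int c = 0; c < ncl; ++c) {
      if (c == own || sz[c] == 0) continue;
      double m = sums[c] / sz[c];
      if (m < b) b = m;
    }
    if (!std::isfinite(b)) { out[i] = 0.0; continue; }
    double mx = std::max(a, b);
    out[i] = (mx > 0.0) ? (b - a) / mx : 0.0;
  }
  return out;
}
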