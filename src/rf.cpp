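#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Minimal classification random forest (two classes, gini splits) with
// out-of-bag permutation importance. Built for small-n feature screening
// inside the Boruta loop; uses R's RNG so results are reproducible under
// set.seed().

namespace {

struct Tree {
  std::vector<int> feat;      // split feature, -1 for leaf
  std::vector<double> thr;    // split threshold (midpoint)
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf prediction (0/1)
};

struct Work {
  const double* X;            // n x p column-major
  const int* y;
  int n, p, mtry, min_node;
  std::vector<int> featbuf;
  std::vector<double> v;      // sort buffer: values
  std::vector<int> c;         // sort buffer: classes
  std::vector<int> ord;
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// grow a node over samples idx[lo:hi), return node id
int grow(Work& wk, std::vector<int>& idx, int lo, int hi, int depth,
         Tree& tr) {
  const int n = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += wk.y[idx[i]];
  const int node = (int)tr.feat.size();
  tr.feat.push_back(-1);
  tr.thr.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.pred.push_back(c1 * 2 > n ? 1 : 0);
  if (c1 == 0 || c1 == n || n < 2 * wk.min_node || depth > 30) return node;

  int best_f = -1;
  double best_thr = 0.0, best_gini = 1e300;
  for (int m = 0; m < wk.mtry; ++m) {
    const int r = m + rand_int(wk.p - m);
    std::swap(wk.featbuf[m], wk.featbuf[r]);
    const int f = wk.featbuf[m];
    const double* col = wk.X + (size_t)f * wk.n;
    for (int i = 0; i < n; ++i) wk.ord[i] = i;
    for (int i = 0; i < n; ++i) {
      const int s = idx[lo + i];
      wk.v[i] = col[s];
      wk.c[i] = wk.y[s];
    }
    // insertion sort of (v, c) by v: cheap at these node sizes
    for (int i = 1; i < n; ++i) {
      const double vi = wk.v[i];
      const int ci = wk.c[i];
      int j = i - 1;
      while (j >= 0 && wk.v[j] > vi) {
        wk.v[j + 1] = wk.v[j];
        wk.c[j + 1] = wk.c[j];
        --j;
      }
      wk.v[j + 1] = vi;
      wk.c[j + 1] = ci;
    }
    int l1 = 0;
    for (int s = 0; s < n - 1; ++s) {
      l1 += wk.c[s];
      if (wk.v[s + 1] <= wk.v[s]) continue;  // tie on value
      const int nl = s + 1, nr = n - nl;
      const int r1 = c1 - l1;
      const double gl = nl - ((double)l1 * l1 + (double)(nl - l1) * (nl - l1)) / nl;
      const double gr = nr - ((double)r1 * r1 + (double)(nr - r1) * (nr - r1)) / nr;
      const double g = gl + gr;
      if (g < best_gini - 1e-12) {
        best_gini = g;
        best_f = f;
        best_thr = (wk.v[s] + wk.v[s + 1]) / 2.0;
      }
    }
  }
  if (best_f < 0) return node;  // no valid split among sampled features

  const double* bcol = wk.X + (size_t)best_f * wk.n;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (bcol[idx[i]] <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;
  tr.feat[node] = best_f;
  tr.thr[node] = best_thr;
  const int l = grow(wk, idx, lo, mid, depth + 1, tr);
  tr.left[node] = l;
  const int r = grow(wk, idx, mid, hi, depth + 1, tr);
  tr.right[node] = r;
  return node;
}

inline int predict_one(const Tree& tr, const double* X, int n, int row,
                       int perm_feat, double perm_val) {
  int node = 0;
  while (tr.feat[node] >= 0) {
    const int f = tr.feat[node];
    const double v = (f == perm_feat) ? perm_val : X[(size_t)f * n + row];
    node = (v <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_importance_cpp(NumericMatrix X, IntegerVector y,
                       int ntree = 500, int mtry = 0, int min_node = 1) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  if (mtry > p) mtry = p;

  std::vector<double> Xv(X.begin(), X.end());
  std::vector<int> yv(y.begin(), y.end());
  Work wk;
  wk.X = Xv.data();
  wk.y = yv.data();
  wk.n = n;
  wk.p = p;
  wk.mtry = mtry;
  wk.min_node = min_node;
  wk.featbuf.resize(p);
  for (int j = 0; j < p; ++j) wk.featbuf[j] = j;
  wk.v.resize(n);
  wk.c.resize(n);
  wk.ord.resize(n);

  NumericVector importance(p);
  double oob_err_sum = 0.0;
  int oob_trees = 0;
  std::vector<int> idx(n), inbag(n), oob, used;
  std::vector<char> is_used(p);
  std::vector<double> permv;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int s = rand_int(n);
      idx[i] = s;
      inbag[s]++;
    }
    Tree tr;
    tr.feat.reserve(2 * n);
    tr.thr.reserve(2 * n);
    tr.left.reserve(2 * n);
    tr.right.reserve(2 * n);
    tr.pred.reserve(2 * n);
    grow(wk, idx, 0, n, 0, tr);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    const int no = (int)oob.size();

    int correct = 0;
    for (int i = 0; i < no; ++i)
      if (predict_one(tr, wk.X, n, oob[i], -1, 0.0) == yv[oob[i]]) ++correct;
    const double acc0 = (double)correct / no;
    oob_err_sum += 1.0 - acc0;
    ++oob_trees;

    // permutation importance only for features the tree actually uses
    std::fill(is_used.begin(), is_used.end(), 0);
    used.clear();
    for (size_t nd = 0; nd < tr.feat.size(); ++nd)
      if (tr.feat[nd] >= 0 && !is_used[tr.feat[nd]]) {
        is_used[tr.feat[nd]] = 1;
        used.push_back(tr.feat[nd]);
      }
    for (size_t u = 0; u < used.size(); ++u) {
      const int f = used[u];
      permv.resize(no);
      for (int i = 0; i < no; ++i) permv[i] = wk.X[(size_t)f * n + oob[i]];
      for (int i = no - 1; i > 0; --i)
        std::swap(permv[i], permv[rand_int(i + 1)]);
      int cp = 0;
      for (int i = 0; i < no; ++i)
        if (predict_one(tr, wk.X, n, oob[i], f, permv[i]) == yv[oob[i]]) ++cp;
      importance[f] += acc0 - (double)cp / no;
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= ntree;
  return List::create(
      _["importance"] = importance,
      _["oob_error"] = oob_trees ? oob_err_sum / oob_trees : NA_REAL);
}
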