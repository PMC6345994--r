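// Random forest with single-feature and feature-difference threshold rules,
// trained by entropy reduction over randomly proposed candidate splits.
// Uses its own splitmix64 RNG so trained models are byte-identical across
// platforms and independent of R's RNG state. Training operates on a
// row-major (sample-contiguous) copy of the per-tree bootstrap sample and
// evaluates all candidates in sample-outer order for cache locality.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Cand {
  int type;  // 0 = single feature, 1 = feature difference
  int i, j;  // 0-based feature indices
  double thr;
};

double entropy_counts(const int* cnt, int K, int n) {
  if (n <= 0) return 0.0;
  double h = 0.0;
  for (int c = 0; c < K; ++c) {
    if (cnt[c] > 0) {
      double p = (double)cnt[c] / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// Row-major training view: x[s * F + f], labels y0 in 0..K-1.
struct Data {
  const double* x;
  const int* y;
  int F, K;
};

inline double expr_of(const Data& d, int s, const Cand& c) {
  const double* row = d.x + (size_t)s * d.F;
  double v = row[c.i];
  if (c.type == 1) v -= row[c.j];
  return v;
}

// true when every feature is constant over the node's samples
bool node_degenerate(const Data& d, const std::vector<int>& idx) {
  const double* r0 = d.x + (size_t)idx[0] * d.F;
  for (size_t k = 1; k < idx.size(); ++k) {
    const double* r = d.x + (size_t)idx[k] * d.F;
    for (int f = 0; f < d.F; ++f) {
      if (r[f] != r0[f]) return false;
    }
  }
  return true;
}

// Draw candidate (type, i, j) tuples, compute per-candidate expression
// min/max over the node in one sample-outer pass, then draw thresholds
// uniformly within each range.
std::vector<Cand> propose(const Data& d, const std::vector<int>& idx,
                          int n_candidates, Rng& rng) {
  std::vector<Cand> out;
  if (idx.size() < 2 || node_degenerate(d, idx)) return out;
  out.resize(n_candidates);
  for (int k = 0; k < n_candidates; ++k) {
    Cand& c = out[k];
    c.type = (d.F > 1 && rng.u01() < 0.5) ? 1 : 0;
    c.i = rng.below(d.F);
    c.j = -1;
    if (c.type == 1) {
      c.j = rng.below(d.F - 1);
      if (c.j >= c.i) ++c.j;
    }
  }
  std::vector<double> lo(n_candidates, R_PosInf), hi(n_candidates, R_NegInf);
  for (int s : idx) {
    const double* row = d.x + (size_t)s * d.F;
    for (int k = 0; k < n_candidates; ++k) {
      const Cand& c = out[k];
      double v = (c.type == 1) ? row[c.i] - row[c.j] : row[c.i];
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  }
  for (int k = 0; k < n_candidates; ++k) {
    out[k].thr = lo[k] + rng.u01() * (hi[k] - lo[k]);
  }
  return out;
}

// index of the best candidate by entropy reduction (first proposed wins
// ties); -1 when no candidate yields positive gain with children of at
// least min_leaf samples
int best_split_idx(const Data& d, const std::vector<int>& idx,
                   const std::vector<Cand>& cands, int min_leaf,
                   double* out_gain) {
  int n = idx.size();
  int K = d.K;
  int nc = cands.size();
  std::vector<int> parent(K, 0);
  for (int s : idx) parent[d.y[s]]++;
  double hp = entropy_counts(parent.data(), K, n);
  // class counts of the left child for every candidate, sample-outer
  std::vector<int> left((size_t)nc * K, 0);
  std::vector<int> nl(nc, 0);
  for (int s : idx) {
    const double* row = d.x + (size_t)s * d.F;
    int cls = d.y[s];
    for (int k = 0; k < nc; ++k) {
      const Cand& c = cands[k];
      double v = (c.type == 1) ? row[c.i] - row[c.j] : row[c.i];
      if (v <= c.thr) {
        left[(size_t)k * K + cls]++;
        nl[k]++;
      }
    }
  }
  int best = -1;
  double best_gain = 1e-12;
  std::vector<int> right(K);
  for (int k = 0; k < nc; ++k) {
    int nr = n - nl[k];
    if (nl[k] < min_leaf || nr < min_leaf || nl[k] == 0 || nr == 0) continue;
    const int* lk = left.data() + (size_t)k * K;
    for (int c = 0; c < K; ++c) right[c] = parent[c] - lk[c];
    double gain = hp - (nl[k] * entropy_counts(lk, K, nl[k]) +
                        nr * entropy_counts(right.data(), K, nr)) / n;
    if (gain > best_gain) {
      best_gain = gain;
      best = k;
    }
  }
  if (best >= 0) *out_gain = best_gain;
  return best;
}

struct TreeBuf {
  std::vector<int> type, fi, fj, left, right, depth;
  std::vector<double> thr, gain;
  std::vector<double> probs;  // n_nodes x K, row-major per node
  int K;
};

int add_leaf(TreeBuf& t, const Data& d, const std::vector<int>& idx,
             int depth) {
  std::vector<int> cnt(t.K, 0);
  for (int s : idx) cnt[d.y[s]]++;
  int id = t.type.size();
  t.type.push_back(-1);
  t.fi.push_back(-1); t.fj.push_back(-1);
  t.thr.push_back(NA_REAL); t.gain.push_back(NA_REAL);
  t.left.push_back(-1); t.right.push_back(-1);
  t.depth.push_back(depth);
  for (int c = 0; c < t.K; ++c) {
    t.probs.push_back((double)cnt[c] / idx.size());
  }
  return id;
}

int grow(TreeBuf& t, const Data& d, const std::vector<int>& idx, int depth,
         int max_depth, int n_candidates, int min_leaf, Rng& rng) {
  bool pure = true;
  for (size_t k = 1; k < idx.size(); ++k) {
    if (d.y[idx[k]] != d.y[idx[0]]) { pure = false; break; }
  }
  if (pure || depth >= max_depth || (int)idx.size() < 2 * min_leaf) {
    return add_leaf(t, d, idx, depth);
  }
  std::vector<Cand> cands = propose(d, idx, n_candidates, rng);
  double gain = 0.0;
  int b = cands.empty() ? -1 : best_split_idx(d, idx, cands, min_leaf, &gain);
  if (b < 0) return add_leaf(t, d, idx, depth);
  const Cand& c = cands[b];
  std::vector<int> li, ri;
  for (int s : idx) {
    if (expr_of(d, s, c) <= c.thr) li.push_back(s);
    else ri.push_back(s);
  }
  int id = t.type.size();
  t.type.push_back(c.type);
  t.fi.push_back(c.i); t.fj.push_back(c.j);
  t.thr.push_back(c.thr); t.gain.push_back(gain);
  t.left.push_back(-2); t.right.push_back(-2);
  t.depth.push_back(depth);
  for (int cc = 0; cc < t.K; ++cc) t.probs.push_back(NA_REAL);
  int l = grow(t, d, li, depth + 1, max_depth, n_candidates, min_leaf, rng);
  int r2 = grow(t, d, ri, depth + 1, max_depth, n_candidates, min_leaf, rng);
  t.left[id] = l;
  t.right[id] = r2;
  return id;
}

List tree_to_list(const TreeBuf& t) {
  int n = t.type.size();
  NumericMatrix probs(n, t.K);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < t.K; ++c) probs(i, c) = t.probs[(size_t)i * t.K + c];
  }
  // 1-based indices for R; 0 marks "none"
  IntegerVector fi(n), fj(n), left(n), right(n);
  for (int i = 0; i < n; ++i) {
    fi[i] = t.fi[i] + 1;
    fj[i] = t.fj[i] + 1;
    left[i] = t.left[i] + 1;
    right[i] = t.right[i] + 1;
  }
  return List::create(_["type"] = IntegerVector(t.type.begin(), t.type.end()),
                      _["i"] = fi, _["j"] = fj,
                      _["threshold"] = NumericVector(t.thr.begin(), t.thr.end()),
                      _["gain"] = NumericVector(t.gain.begin(), t.gain.end()),
                      _["left"] = left, _["right"] = right,
                      _["depth"] = IntegerVector(t.depth.begin(), t.depth.end()),
                      _["probs"] = probs);
}

// row-major copy of selected rows of an R (column-major) matrix
void copy_rows_rowmajor(const NumericMatrix& X, const std::vector<int>& rows,
                        std::vector<double>& out) {
  int F = X.ncol();
  int N = X.nrow();
  out.resize((size_t)rows.size() * F);
  const double* xp = X.begin();
  for (size_t s = 0; s < rows.size(); ++s) {
    double* dst = out.data() + s * F;
    int r = rows[s];
    for (int f = 0; f < F; ++f) dst[f] = xp[r + (size_t)f * N];
  }
}

uint64_t mix_seed(double seed, int stream) {
  uint64_t s = (uint64_t)(int64_t)seed;
  s ^= 0x9e3779b97f4a7c15ULL * (uint64_t)(stream + 1);
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_propose(NumericMatrix X, IntegerVector idx, int n_candidates,
                 double seed) {
  Rng rng(mix_seed(seed, 0));
  std::vector<int> rows(idx.size());
  for (int k = 0; k < idx.size(); ++k) rows[k] = idx[k] - 1;
  std::vector<double> xb;
  copy_rows_rowmajor(X, rows, xb);
  std::vector<int> yb(rows.size(), 0);
  Data d{xb.data(), yb.data(), X.ncol(), 1};
  std::vector<int> local(rows.size());
  for (size_t k = 0; k < rows.size(); ++k) local[k] = k;
  std::vector<Cand> c = propose(d, local, n_candidates, rng);
  int n = c.size();
  IntegerVector type(n), i(n), j(n);
  NumericVector thr(n);
  for (int k = 0; k < n; ++k) {
    type[k] = c[k].type;
    i[k] = c[k].i + 1;
    j[k] = c[k].j + 1;
    thr[k] = c[k].thr;
  }
  return List::create(_["type"] = type, _["i"] = i, _["j"] = j,
                      _["threshold"] = thr);
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, int K,
                    IntegerVector idx, List cand, int min_leaf) {
  IntegerVector type = cand["type"], ci = cand["i"], cj = cand["j"];
  NumericVector thr = cand["threshold"];
  std::vector<Cand> cs(type.size());
  for (int k = 0; k < type.size(); ++k) {
    cs[k].type = type[k];
    cs[k].i = ci[k] - 1;
    cs[k].j = cj[k] - 1;
    cs[k].thr = thr[k];
  }
  std::vector<int> rows(idx.size());
  for (int k = 0; k < idx.size(); ++k) rows[k] = idx[k] - 1;
  std::vector<double> xb;
  copy_rows_rowmajor(X, rows, xb);
  std::vector<int> yb(rows.size());
  for (size_t k = 0; k < rows.size(); ++k) yb[k] = y[rows[k]];
  Data d{xb.data(), yb.data(), X.ncol(), K};
  std::vector<int> local(rows.size());
  for (size_t k = 0; k < rows.size(); ++k) local[k] = k;
  double gain = 0.0;
  int b = best_split_idx(d, local, cs, min_leaf, &gain);
  return List::create(_["index"] = b + 1, _["gain"] = gain);
}

// [[Rcpp::export]]
List cpp_train_tree(NumericMatrix X, IntegerVector y, int K, int max_depth,
                    int n_candidates, int min_leaf, double seed) {
  Rng rng(mix_seed(seed, 0));
  std::vector<int> rows(X.nrow());
  for (int r = 0; r < X.nrow(); ++r) rows[r] = r;
  std::vector<double> xb;
  copy_rows_rowmajor(X, rows, xb);
  std::vector<int> yb(y.begin(), y.end());
  Data d{xb.data(), yb.data(), X.ncol(), K};
  TreeBuf t;
  t.K = K;
  grow(t, d, rows, 0, max_depth, n_candidates, min_leaf, rng);
  return tree_to_list(t);
}

// [[Rcpp::export]]
List cpp_train_forest(NumericMatrix X, IntegerVector y, int K, int n_trees,
                      int max_depth, int n_candidates, int sample_cap,
                      int min_leaf, double seed) {
  int N = X.nrow();
  int F = X.ncol();
  // class index lists for the stratified bootstrap
  std::vector<std::vector<int> > by_class(K);
  for (int r = 0; r < N; ++r) by_class[y[r]].push_back(r);
  int n_samp = std::min(sample_cap, N);
  // per-class allocation proportional to class frequency (largest remainders)
  std::vector<int> alloc(K, 0);
  std::vector<std::pair<double, int> > rem;
  int used = 0;
  for (int c = 0; c < K; ++c) {
    double exact = (double)n_samp * by_class[c].size() / N;
    alloc[c] = (int)std::floor(exact);
    if (!by_class[c].empty() && alloc[c] == 0) alloc[c] = 1;
    used += alloc[c];
    rem.push_back(std::make_pair(exact - std::floor(exact), c));
  }
  std::sort(rem.begin(), rem.end(),
            [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
              return a.first > b.first ||
                     (a.first == b.first && a.second < b.second);
            });
  for (size_t k = 0; used < n_samp && k < rem.size(); ++k) {
    if (!by_class[rem[k].second].empty()) { alloc[rem[k].second]++; ++used; }
  }
  List trees(n_trees);
  std::vector<double> xb;
  std::vector<int> yb, boot;
  for (int t = 0; t < n_trees; ++t) {
    Rng rng(mix_seed(seed, t));
    boot.clear();
    for (int c = 0; c < K; ++c) {
      int nc = by_class[c].size();
      for (int k = 0; k < alloc[c]; ++k) {
        boot.push_back(by_class[c][rng.below(nc)]);
      }
    }
    copy_rows_rowmajor(X, boot, xb);
    yb.resize(boot.size());
    for (size_t s = 0; s < boot.size(); ++s) yb[s] = y[boot[s]];
    Data d{xb.data(), yb.data(), F, K};
    std::vector<int> local(boot.size());
    for (size_t s = 0; s < boot.size(); ++s) local[s] = s;
    TreeBuf tb;
    tb.K = K;
    grow(tb, d, local, 0, max_depth, n_candidates, min_leaf, rng);
    trees[t] = tree_to_list(tb);
    Rcpp::checkUserInterrupt();
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_proba(List trees, NumericMatrix X, int K) {
  int N = X.nrow();
  int F = X.ncol();
  NumericMatrix out(N, K);
  int T = trees.size();
  // row-major copy of the query points for locality
  std::vector<int> all(N);
  for (int r = 0; r < N; ++r) all[r] = r;
  std::vector<double> xb;
  copy_rows_rowmajor(X, all, xb);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector type = tr["type"], fi = tr["i"], fj = tr["j"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"];
    NumericMatrix probs = tr["probs"];
    for (int r = 0; r < N; ++r) {
      const double* row = xb.data() + (size_t)r * F;
      int node = 0;
      while (type[node] >= 0) {
        double v = row[fi[node] - 1];
        if (type[node] == 1) v -= row[fj[node] - 1];
        node = (v <= thr[node]) ? left[node] - 1 : right[node] - 1;
      }
      for (int c = 0; c < K; ++c) out(r, c) += probs(node, c);
    }
    Rcpp::checkUserInterrupt();
  }
  for (int r = 0; r < N; ++r) {
    for (int c = 0; c < K; ++c) out(r, c) /= T;
  }
  return out;
}

// ---- k-means Lloyd updates ----
// Assignment and centroid update with fixed iteration count; empty clusters
// are re-seeded with the point farthest from its current centroid. No RNG:
// fully determined by the initial centroids.

// [[Rcpp::export]]
List cpp_kmeans_lloyd(NumericMatrix X, NumericMatrix C0, int n_iter) {
  int N = X.nrow(), B = X.ncol(), k = C0.nrow();
  std::vector<double> xb;
  std::vector<int> all(N);
  for (int r = 0; r < N; ++r) all[r] = r;
  copy_rows_rowmajor(X, all, xb);
  std::vector<double> cent((size_t)k * B);
  for (int j = 0; j < k; ++j) {
    for (int b = 0; b < B; ++b) cent[(size_t)j * B + b] = C0(j, b);
  }
  std::vector<int> assign(N);
  std::vector<double> dist(N);
  NumericVector inertia(n_iter);

  auto assign_all = [&]() {
    for (int r = 0; r < N; ++r) {
      const double* row = xb.data() + (size_t)r * B;
      double bestd = R_PosInf;
      int bestj = 0;
      for (int j = 0; j < k; ++j) {
        const double* cj = cent.data() + (size_t)j * B;
        double d = 0.0;
        for (int b = 0; b < B; ++b) {
          double t = row[b] - cj[b];
          d += t * t;
        }
        if (d < bestd) { bestd = d; bestj = j; }
      }
      assign[r] = bestj;
      dist[r] = bestd;
    }
  };

  assign_all();
  std::vector<double> sums((size_t)k * B);
  std::vector<int> counts(k);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(counts.begin(), counts.end(), 0);
    for (int r = 0; r < N; ++r) {
      const double* row = xb.data() + (size_t)r * B;
      double* sj = sums.data() + (size_t)assign[r] * B;
      for (int b = 0; b < B; ++b) sj[b] += row[b];
      counts[assign[r]]++;
    }
    for (int j = 0; j < k; ++j) {
      if (counts[j] > 0) {
        for (int b = 0; b < B; ++b) {
          cent[(size_t)j * B + b] = sums[(size_t)j * B + b] / counts[j];
        }
      }
    }
    for (int j = 0; j < k; ++j) {
      if (counts[j] == 0) {
        // farthest point from its current centroid takes over
        int far = 0;
        double fd = -1.0;
        for (int r = 0; r < N; ++r) {
          if (dist[r] > fd) { fd = dist[r]; far = r; }
        }
        const double* row = xb.data() + (size_t)far * B;
        for (int b = 0; b < B; ++b) cent[(size_t)j * B + b] = row[b];
        assign[far] = j;
        dist[far] = 0.0;  // cannot be picked again this round
      }
    }
    assign_all();
    double in = 0.0;
    for (int r = 0; r < N; ++r) in += dist[r];
    inertia[it] = in;
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix C(k, B);
  for (int j = 0; j < k; ++j) {
    for (int b = 0; b < B; ++b) C(j, b) = cent[(size_t)j * B + b];
  }
  IntegerVector a(N);
  for (int r = 0; r < N; ++r) a[r] = assign[r] + 1;
  return List::create(_["centroids"] = C, _["assign"] = a,
                      _["inertia"] = inertia);
}

// nearest-centroid assignment (ties to the lowest index)
// [[Rcpp::export]]
IntegerVector cpp_assign_nearest(NumericMatrix X, NumericMatrix C) {
  int N = X.nrow(), B = X.ncol(), k = C.nrow();
  std::vector<double> xb;
  std::vector<int> all(N);
  for (int r = 0; r < N; ++r) all[r] = r;
  copy_rows_rowmajor(X, all, xb);
  std::vector<double> cb;
  std::vector<int> allc(k);
  for (int j = 0; j < k; ++j) allc[j] = j;
  copy_rows_rowmajor(C, allc, cb);
  IntegerVector out(N);
  for (int r = 0; r < N; ++r) {
    const double* row = xb.data() + (size_t)r * B;
    double bestd = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < k; ++j) {
      const double* cj = cb.data() + (size_t)j * B;
      double d = 0.0;
      for (int b = 0; b < B; ++b) {
        double t = row[b] - cj[b];
        d += t * t;
      }
      if (d < bestd) { bestd = d; bestj = j; }
    }
    out[r] = bestj + 1;
  }
  return out;
}
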