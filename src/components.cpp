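#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Single column-major sweep; neighbours already visited are (i-1,j),
// (i-1,j-1), (i,j-1), (i+1,j-1); the last two diagonals only at
// 8-connectivity.
static void uf_pass(const int nr, const int nc,
                    const std::function<bool(int, int)> &fg,
                    int connectivity, std::vector<int> &parent) {
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!fg(i, j)) continue;
      int id = i + j * nr;
      parent[id] = id;
      if (i > 0 && fg(i - 1, j)) uf_union(parent, id, id - 1);
      if (j > 0) {
        if (fg(i, j - 1)) uf_union(parent, id, id - nr);
        if (connectivity == 8) {
          if (i > 0 && fg(i - 1, j - 1)) uf_union(parent, id, id - nr - 1);
          if (i < nr - 1 && fg(i + 1, j - 1)) uf_union(parent, id, id - nr + 1);
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> parent(static_cast<size_t>(nr) * nc, -1);
  auto fg = [&](int i, int j) { return mask(i, j) == TRUE; };
  uf_pass(nr, nc, fg, connectivity, parent);

  IntegerMatrix labels(nr, nc);
  std::vector<int> relab(static_cast<size_t>(nr) * nc, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = i + j * nr;
      if (parent[id] < 0) continue;
      int r = uf_find(parent, id);
      if (relab[r] == 0) relab[r] = ++next;
      labels(i, j) = relab[r];
    }
  }
  return labels;
}

// Per-threshold counts of multi-pixel (>= 2 px) and single-pixel connected
// components of the mask {x > t}, for every threshold t (thresholds must be
// sorted ascending). One incremental union-find pass: pixels are activated
// in descending DN order, so the counts for all thresholds come out of a
// single O(N log N) sweep instead of one labelling per threshold.
// [[Rcpp::export]]
IntegerMatrix threshold_counts_cpp(NumericMatrix x, NumericVector thresholds,
                                   int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  const size_t n = static_cast<size_t>(nr) * nc;
  const int nt = thresholds.size();
  IntegerMatrix out(nt, 2);

  std::vector<int> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = static_cast<int>(i);
  const double *xv = x.begin();
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return xv[a] > xv[b]; });

  std::vector<int> parent(n, -1);
  std::vector<int> csize(n, 0);
  int nMulti = 0, nSingle = 0;

  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;

  size_t next = 0;
  for (int t = nt - 1; t >= 0; --t) {
    const double thr = thresholds[t];
    while (next < n && xv[order[next]] > thr) {
      const int id = order[next++];
      const int i = id % nr, j = id / nr;
      parent[id] = id;
      csize[id] = 1;
      ++nSingle;
      for (int k = 0; k < nnb; ++k) {
        const int ni = i + di8[k], nj = j + dj8[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        const int nid = ni + nj * nr;
        if (parent[nid] < 0) continue;
        int ra = uf_find(parent, id), rb = uf_find(parent, nid);
        if (ra == rb) continue;
        const int sa = csize[ra], sb = csize[rb];
        if (sa == 1 && sb == 1) { nSingle -= 2; ++nMulti; }
        else if (sa == 1 || sb == 1) { --nSingle; }
        else { --nMulti; }
        const int root = std::min(ra, rb), child = std::max(ra, rb);
        parent[child] = root;
        csize[root] = sa + sb;
      }
    }
    out(t, 0) = nMulti;
    out(t, 1) = nSingle;
  }
  return out;
}
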