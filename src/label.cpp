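#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' @title Connected-component labeling (internal)
//' @description Two-pass union-find labeling of a binary matrix with 4- or
//'   8-connectivity. Labels are renumbered 1..K in column-major first-touch
//'   order, so the result is deterministic for a given input.
//' @param mask logical matrix (NA treated as background)
//' @param connectivity 4 or 8
//' @return integer matrix of labels, 0 for background
//' @keywords internal
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;  // 0-based provisional ids; lab stores id+1, 0 = background

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != TRUE) { lab(i, j) = 0; continue; }
      // previously-scanned neighbours in column-major order:
      // (i-1, j) same column above; (i, j-1), and diagonals in column j-1
      int best = -1;
      int cand[4][2] = { {i - 1, j}, {i, j - 1}, {i - 1, j - 1}, {i + 1, j - 1} };
      int ncand = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < ncand; ++k) {
        int ci = cand[k][0], cj = cand[k][1];
        if (ci < 0 || ci >= nr || cj < 0) continue;
        int l = lab(ci, cj);
        if (l > 0) {
          int root = uf_find(parent, l - 1);
          if (best < 0) best = root;
          else if (root != best) { uf_union(parent, best, root); best = std::min(best, root); }
        }
      }
      if (best < 0) {
        parent.push_back(next);
        lab(i, j) = ++next;  // stores next (1-based)
      } else {
        lab(i, j) = best + 1;
      }
    }
  }

  // Resolve and renumber in column-major first-touch order.
  std::vector<int> newlab(next, 0);
  int K = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int root = uf_find(parent, l - 1);
      if (newlab[root] == 0) newlab[root] = ++K;
      lab(i, j) = newlab[root];
    }
  }
  return lab;
}

//' @title Fill small interior holes (internal)
//' @description Labels the complement of \code{mask} with the dual
//'   connectivity (4 when the foreground is 8-connected and vice versa) and
//'   fills every background component that does not touch the image border and
//'   whose area is at most \code{max_hole}.
//' @keywords internal
// [[Rcpp::export(name = ".cc_fill_holes")]]
LogicalMatrix cc_fill_holes(LogicalMatrix mask, double max_hole, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix inv(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      inv(i, j) = (mask(i, j) == TRUE) ? FALSE : TRUE;
  int dual = (connectivity == 8) ? 4 : 8;
  IntegerMatrix lab = cc_label(inv, dual);
  int K = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > K) K = lab(i, j);
  std::vector<double> area(K + 1, 0.0);
  std::vector<bool> border(K + 1, false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      area[l] += 1.0;
      if (i == 0 || j == 0 || i == nr - 1 || j == nc - 1) border[l] = true;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      bool fg = (mask(i, j) == TRUE);
      if (!fg && l > 0 && !border[l] && area[l] <= max_hole) fg = true;
      out(i, j) = fg;
    }
  }
  return out;
}
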