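#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offsets P2..P9, clockwise from north (Zhang-Suen convention).
static const int NR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int NC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// B(p): number of foreground 8-neighbours.
static inline int bsum(const IntegerMatrix &m, int r, int c) {
  int s = 0;
  for (int k = 0; k < 8; ++k) s += px(m, r + NR[k], c + NC[k]);
  return s;
}

// A(p): number of 0->1 transitions in the sequence P2,...,P9,P2.
static inline int across(const IntegerMatrix &m, int r, int c) {
  int a = 0;
  for (int k = 0; k < 8; ++k) {
    int cur = px(m, r + NR[k], c + NC[k]);
    int nxt = px(m, r + NR[(k + 1) % 8], c + NC[(k + 1) % 8]);
    if (cur == 0 && nxt == 1) ++a;
  }
  return a;
}

// Number of 8-connected groups formed by the foreground neighbours of
// (r, c) among themselves (the centre excluded).
static int neighbour_groups(const IntegerMatrix &m, int r, int c) {
  int pr[8], pc[8], n = 0;
  for (int k = 0; k < 8; ++k)
    if (px(m, r + NR[k], c + NC[k])) { pr[n] = r + NR[k]; pc[n] = c + NC[k]; ++n; }
  if (n == 0) return 0;
  int grp[8];
  for (int i = 0; i < n; ++i) grp[i] = i;
  bool merged = true;
  while (merged) {
    merged = false;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (grp[i] != grp[j] &&
            std::abs(pr[i] - pr[j]) <= 1 && std::abs(pc[i] - pc[j]) <= 1) {
          int from = grp[j], to = grp[i];
          for (int k = 0; k < n; ++k) if (grp[k] == from) grp[k] = to;
          merged = true;
        }
  }
  int ng = 0;
  for (int i = 0; i < n; ++i) if (grp[i] == i) ++ng;
  return ng;
}

static inline bool zs_deletable(const IntegerMatrix &m, int r, int c, int pass) {
  if (px(m, r, c) == 0) return false;
  int b = bsum(m, r, c);
  if (b < 2 || b > 6) return false;
  if (across(m, r, c) != 1) return false;
  int p2 = px(m, r - 1, c), p4 = px(m, r, c + 1);
  int p6 = px(m, r + 1, c), p8 = px(m, r, c - 1);
  if (pass == 0) {
    if (p2 * p4 * p6 != 0) return false;
    if (p4 * p6 * p8 != 0) return false;
  } else {
    if (p2 * p4 * p8 != 0) return false;
    if (p2 * p6 * p8 != 0) return false;
  }
  return true;
}

// Zhang-Suen thinning. Candidates are marked in parallel per sub-iteration,
// then deleted sequentially with a re-check against the current image so
// that connectivity is never broken (the purely parallel variant can erase
// an isolated 2x2 block entirely).
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<int> cand_r, cand_c;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      cand_r.clear(); cand_c.clear();
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          if (zs_deletable(m, r, c, pass)) { cand_r.push_back(r); cand_c.push_back(c); }
      for (size_t i = 0; i < cand_r.size(); ++i) {
        int r = cand_r[i], c = cand_c[i];
        if (zs_deletable(m, r, c, pass)) { m(r, c) = 0; changed = true; }
      }
    }
  }
  // Reduce to a minimal 8-curve: Zhang-Suen leaves staircase corner
  // pixels on oblique runs (and can leave 2x2 blocks), which would make
  // ordinary curve pixels look like branch points. A non-endpoint pixel
  // whose foreground neighbours form a single 8-connected group is
  // redundant -- deleting it cannot disconnect anything -- so prune all
  // such pixels until stable.
  bool pruned = true;
  while (pruned) {
    pruned = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (!m(r, c) || bsum(m, r, c) < 2) continue;
        if (neighbour_groups(m, r, c) == 1) { m(r, c) = 0; pruned = true; }
      }
  }
  return m;
}

// Connected-component labelling by flood fill; connectivity 4 or 8.
// Returns 0 for background, 1..k component labels in scan order.
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 4) ? 4 : 8;
  static const int R4[8] = {-1, 0, 1, 0, -1, -1, 1, 1};
  static const int C4[8] = {0, 1, 0, -1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + R4[k], c2 = cc + C4[k];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  return lab;
}

// Count of foreground 8-neighbours for every pixel (used for branch points).
// [[Rcpp::export(name = ".neighbour_count_cpp")]]
IntegerMatrix neighbour_count_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = bsum(mask, r, c);
  return out;
}
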