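#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-pass connected-component labelling, 8-connectivity, union-find.
// mask is logical [nrow x ncol]; returns integer labels (0 = background),
// labels are 1..k in order of first (column-major) appearance.

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label_(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // dummy so labels are 1-based
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // previously visited 8-neighbours in column-major scan order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
      }
    }
  }
  // resolve + relabel densely in order of appearance
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = uf_find(parent, lab(r, c));
        if (remap[root] == 0) remap[root] = ++k;
        lab(r, c) = remap[root];
      }
  return lab;
}

// Zhang-Suen thinning to a 1-px skeleton (8-connected medial axis
// approximation). Iterates until stable.
// [[Rcpp::export]]
LogicalMatrix thin_mask_(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // pad by one to avoid bounds checks
  std::vector<unsigned char> img((nr + 2) * (nc + 2), 0);
  auto at = [&](int r, int c) -> unsigned char & {
    return img[(size_t)(c) * (nr + 2) + r];
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      at(r + 1, c + 1) = mask(r, c) ? 1 : 0;

  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c <= nc; ++c) {
        for (int r = 1; r <= nr; ++r) {
          if (!at(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          unsigned char p2 = at(r - 1, c), p3 = at(r - 1, c + 1),
                        p4 = at(r, c + 1), p5 = at(r + 1, c + 1),
                        p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
                        p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        at(kill[i].first, kill[i].second) = 0;
    }
  }
  // Redundancy pruning: Zhang-Suen can leave staircase corners and
  // 2-px-thick diagonal runs, which inflate adjacency-step counts.
  // Sequentially remove any non-endpoint pixel whose foreground
  // neighbours remain mutually 8-connected without it (local
  // simple-point test on the ring), until stable.
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 1; c <= nc; ++c) {
      for (int r = 1; r <= nr; ++r) {
        if (!at(r, c)) continue;
        int pr[8], pc[8], np = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            if (at(r + dr, c + dc)) { pr[np] = dr; pc[np] = dc; ++np; }
          }
        if (np < 2) continue; // endpoint or isolated: keep
        int comp[8];
        for (int i = 0; i < np; ++i) comp[i] = i;
        for (int i = 0; i < np; ++i)
          for (int j = i + 1; j < np; ++j)
            if (std::abs(pr[i] - pr[j]) <= 1 && std::abs(pc[i] - pc[j]) <= 1) {
              int ci = comp[i], cj = comp[j];
              if (ci != cj)
                for (int k = 0; k < np; ++k)
                  if (comp[k] == cj) comp[k] = ci;
            }
        bool one = true;
        for (int i = 1; i < np; ++i) if (comp[i] != comp[0]) one = false;
        if (one) { at(r, c) = 0; changed = true; }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = at(r + 1, c + 1) != 0;
  return out;
}

// Exact Euclidean distance from each query pixel to the nearest reference
// pixel. query, ref: two-column integer matrices of (row, col). Brute force
// with running-minimum pruning; adequate for rhizobox-stride sized masks.
// [[Rcpp::export]]
NumericVector nearest_dist_(IntegerMatrix query, IntegerMatrix ref) {
  int nq = query.nrow(), nref = ref.nrow();
  NumericVector out(nq);
  if (nref == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    double qr = query(i, 0), qc = query(i, 1);
    for (int j = 0; j < nref; ++j) {
      double dr = qr - ref(j, 0), dc = qc - ref(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
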