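#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of the nonzero pixels of an image matrix.
// Two-pass union-find; labels are 1..k in raster (column-major) discovery
// order of each component's first pixel. Background (zero/NA) stays 0.
// [[Rcpp::export(name = ".label_cc8")]]
IntegerMatrix label_cc8(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (!(v != 0) || NumericMatrix::is_na(v)) continue;
      // previously visited 8-neighbours (column-major scan):
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int best = 0;
      int ni[4] = {i - 1, i - 1, i, i + 1};
      int nj[4] = {j, j - 1, j - 1, j - 1};
      for (int k = 0; k < 4; ++k) {
        if (ni[k] < 0 || ni[k] >= nr || nj[k] < 0) continue;
        int l = lab(ni[k], nj[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = find(best);
      }
    }
  }
  // flatten and renumber compactly in first-appearance order
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find(l);
      if (remap[r] == 0) remap[r] = ++k;
      lab(i, j) = remap[r];
    }
  return lab;
}

// Per-row mode of an integer matrix with values in [0, 255].
// Ties resolved toward the smallest value. Used by the background model:
// rows are pixels, columns are sampled frames.
// [[Rcpp::export(name = ".row_mode_u8")]]
IntegerVector row_mode_u8(IntegerMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerVector out(nr);
  std::vector<int> count(256);
  for (int i = 0; i < nr; ++i) {
    std::fill(count.begin(), count.end(), 0);
    for (int j = 0; j < nc; ++j) {
      int v = x(i, j);
      if (v == NA_INTEGER) continue;
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      ++count[v];
    }
    int best = 0, bestn = -1;
    for (int v = 0; v < 256; ++v)
      if (count[v] > bestn) { bestn = count[v]; best = v; }
    out[i] = best;
  }
  return out;
}
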