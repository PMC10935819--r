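#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label connected components of a binary mask.
//'
//' Two-pass union-find labelling. Foreground is any non-zero entry.
//' Labels are positive integers; background stays 0. Label order follows
//' the first (column-major) foreground pixel of each component.
//'
//' @param mask integer matrix of 0/1
//' @param connectivity 4 or 8
//' @return integer matrix of component labels
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (H == 0 || W == 0) return lab;
  std::vector<int> parent(static_cast<size_t>(H) * W);

  // Pass 1: provisional label = own linear index; union with prior neighbours.
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      const int idx = j * H + i;
      parent[idx] = idx;
      if (i > 0 && mask(i - 1, j) != 0) uf_union(parent, idx, idx - 1);
      if (j > 0 && mask(i, j - 1) != 0) uf_union(parent, idx, idx - H);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1) != 0) uf_union(parent, idx, idx - H - 1);
        if (i < H - 1 && mask(i + 1, j - 1) != 0) uf_union(parent, idx, idx - H + 1);
      }
    }
  }

  // Pass 2: compress roots to consecutive labels.
  std::vector<int> root_label(static_cast<size_t>(H) * W, 0);
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      const int idx = j * H + i;
      const int r = uf_find(parent, idx);
      if (root_label[r] == 0) root_label[r] = ++next;
      lab(i, j) = root_label[r];
    }
  }
  return lab;
}
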