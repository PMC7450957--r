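#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of a binary mask by breadth-first search.
// Components are numbered 1..k in column-major scan order of their first
// pixel, so labels are deterministic for a given mask. connectivity is 4
// (edge neighbours) or 8 (edge + diagonal neighbours).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W); // 0 = unlabelled / background
  std::vector<int> qi(static_cast<size_t>(H) * W), qj(static_cast<size_t>(H) * W);
  const int di8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dj8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = i; qj[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        const int ci = qi[head], cj = qj[head]; ++head;
        for (int k = 0; k < nd; ++k) {
          const int ni = ci + di8[k], nj = cj + dj8[k];
          if (ni >= 0 && ni < H && nj >= 0 && nj < W &&
              mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi[tail] = ni; qj[tail] = nj; ++tail;
          }
        }
      }
    }
  }
  return lab;
}
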