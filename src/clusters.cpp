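#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling of a logical matrix. Returns an integer
// matrix with 0 for unmarked cells and 1..K for component membership.
// [[Rcpp::export]]
IntegerMatrix cluster_label_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(64);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
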