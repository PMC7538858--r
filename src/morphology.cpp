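#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a binary image by breadth-first flood
// fill. connectivity must be 4 or 8. Returns an integer matrix of labels
// (0 = background, components numbered 1..k in raster-scan discovery
// order), so label ids are deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || labels(i, j) != 0) continue;
      ++next;
      labels(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qi = pi + dr8[k], qj = pj + dc8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && labels(qi, qj) == 0) {
            labels(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return labels;
}
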