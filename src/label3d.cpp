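#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 26-connectivity component labelling of a 3D logical array, BFS with an
// explicit stack. Labels are 1..K in discovery (lexicographic seed) order;
// background is 0.

// [[Rcpp::export(name = ".label3_cpp")]]
IntegerVector label3_cpp(LogicalVector mask, IntegerVector dims) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (mask[seed] != TRUE || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i0 = (int)(p % d0);
      int i1 = (int)((p / d0) % d1);
      int i2 = (int)(p / ((R_xlen_t)d0 * d1));
      for (int a = -1; a <= 1; ++a) {
        int j2 = i2 + a;
        if (j2 < 0 || j2 >= d2) continue;
        for (int b = -1; b <= 1; ++b) {
          int j1 = i1 + b;
          if (j1 < 0 || j1 >= d1) continue;
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            int j0 = i0 + c;
            if (j0 < 0 || j0 >= d0) continue;
            R_xlen_t q = j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2);
            if (mask[q] == TRUE && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}
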