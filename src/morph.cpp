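#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stack-based flood fill shared by the labelling and hole-filling routines.
// Grids are column-major (R layout); connectivity is 4 or 8 in-plane.

static const int DR8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DC8[8] = {0, 0, 1, -1, 1, -1, 1, -1};

static void flood(const int *mask, int *lab, int nr, int nc,
                  int si, int sj, int label, int nn,
                  std::vector<int> &stack) {
  stack.clear();
  lab[si + sj * nr] = label;
  stack.push_back(si + sj * nr);
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int k = 0; k < nn; ++k) {
      int qi = pi + DR8[k], qj = pj + DC8[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int q = qi + qj * nr;
      if (mask[q] != 0 && lab[q] == 0) {
        lab[q] = label;
        stack.push_back(q);
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".labelComponents2D")]]
IntegerMatrix labelComponents2D(IntegerMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) != 0 && lab(i, j) == 0)
        flood(mask.begin(), lab.begin(), nr, nc, i, j, ++next,
              connectivity, stack);
  return lab;
}

// Hole filling: background components not reachable from the image border
// become foreground.  The background is traversed with the connectivity
// dual to the foreground one (8 -> 4, 4 -> 8), the usual digital-topology
// convention that keeps foreground and holes consistent.

//' @noRd
// [[Rcpp::export(name = ".fillHoles2D")]]
IntegerMatrix fillHoles2D(IntegerMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int bgConn = (connectivity == 8) ? 4 : 8;
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> bg(nr * nc), reach(nr * nc, 0);
  for (int k = 0; k < nr * nc; ++k) bg[k] = mask[k] == 0 ? 1 : 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (i != 0 && i != nr - 1 && j != 0 && j != nc - 1) continue;
      int p = i + j * nr;
      if (bg[p] && !reach[p])
        flood(bg.data(), reach.data(), nr, nc, i, j, 1, bgConn, stack);
    }
  IntegerMatrix out(nr, nc);
  for (int k = 0; k < nr * nc; ++k)
    out[k] = (mask[k] != 0 || (bg[k] && !reach[k])) ? 1 : 0;
  return out;
}
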