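#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Cumulative scoring matrix for the gap-free local recurrence:
//   H[i, j] = max(H[i-1, j-1] + S[i-1, j-1], H[i-1, j], H[i, j-1])
// with the first row and column fixed at zero. Gap moves carry no penalty,
// so H is non-decreasing along rows and columns and never negative.
// [[Rcpp::export(name = ".fill_scoring_cpp")]]
NumericMatrix fill_scoring_cpp(NumericMatrix S) {
  const int n = S.nrow(), k = S.ncol();
  NumericMatrix H(n + 1, k + 1); // zero-initialised
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= k; ++j) {
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double u = H(i - 1, j);
      double l = H(i, j - 1);
      double v = d > u ? d : u;
      if (l > v) v = l;
      H(i, j) = v;
    }
  }
  return H;
}

// Multi-start traceback: one walk per border cell of H (bottom row and
// rightmost column, shared corner used once). Each walk repeatedly moves to
// the argmax predecessor (tie order: diagonal, vertical, horizontal) and
// stops on a non-positive cumulative score or at a matrix edge. Cells are
// emitted as 1-based (query, target) residue indices in N-to-C order.
// [[Rcpp::export(name = ".traceback_cpp")]]
List traceback_cpp(NumericMatrix H) {
  const int n = H.nrow() - 1, k = H.ncol() - 1;
  std::vector<std::pair<int, int> > starts;
  starts.reserve(n + k - 1);
  for (int j = 1; j <= k; ++j) starts.push_back(std::make_pair(n, j));
  for (int i = 1; i <= n - 1; ++i) starts.push_back(std::make_pair(i, k));

  List out;
  std::vector<int> ci, cj;
  for (size_t s = 0; s < starts.size(); ++s) {
    int i = starts[s].first, j = starts[s].second;
    ci.clear();
    cj.clear();
    while (i >= 1 && j >= 1) {
      if (H(i, j) <= 0.0) break;
      ci.push_back(i);
      cj.push_back(j);
      double d = H(i - 1, j - 1);
      double u = H(i - 1, j);
      double l = H(i, j - 1);
      if (d >= u && d >= l) { --i; --j; }
      else if (u >= l)      { --i; }
      else                  { --j; }
    }
    if (ci.empty()) continue;
    const int L = (int) ci.size();
    IntegerMatrix cells(L, 2);
    for (int t = 0; t < L; ++t) { // reverse into N-to-C order
      cells(L - 1 - t, 0) = ci[t];
      cells(L - 1 - t, 1) = cj[t];
    }
    out.push_back(cells);
  }
  return out;
}
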