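#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global edit-distance search of an adapter against a read,
// "back" orientation: an adapter *prefix* aligned inside the read, with
// a free start anywhere in the read. Candidate occurrences are either
// the full adapter anywhere in the read, or a partial adapter prefix
// whose alignment reaches the read's 3' end. A hit is accepted when the
// aligned adapter length is at least min_overlap and the edit distance
// is at most floor(max_err_frac * aligned length). Among acceptable
// hits the one maximizing (aligned length - 4 * errors) wins; ties go
// to the leftmost read start (removing the most sequence).
//
// Returns c(start, end, errors, matched) in 0-based half-open read
// coordinates, or c(-1, -1, -1, -1) when nothing acceptable is found.
// [[Rcpp::export(name = ".adapter_hit_back")]]
IntegerVector adapter_hit_back(std::string read, std::string adapter,
                               int min_overlap, double max_err_frac) {
  int n = read.size(), m = adapter.size();
  IntegerVector none = IntegerVector::create(-1, -1, -1, -1);
  if (n == 0 || m == 0) return none;
  std::vector<int> prevD(n + 1), curD(n + 1), prevS(n + 1), curS(n + 1);
  for (int j = 0; j <= n; ++j) { prevD[j] = 0; prevS[j] = j; }
  int best_score = INT_MIN, best_start = -1, best_end = -1,
      best_err = -1, best_len = -1;
  for (int i = 1; i <= m; ++i) {
    curD[0] = i; curS[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int sub = prevD[j - 1] + (adapter[i - 1] == read[j - 1] ? 0 : 1);
      int del = prevD[j] + 1;   // gap in read
      int ins = curD[j - 1] + 1; // gap in adapter
      int d = sub, s = prevS[j - 1];
      if (del < d) { d = del; s = prevS[j]; }
      if (ins < d) { d = ins; s = curS[j - 1]; }
      // deterministic tie-break: prefer the smaller start
      if (sub == d && prevS[j - 1] < s) s = prevS[j - 1];
      if (del == d && prevS[j] < s) s = prevS[j];
      if (ins == d && curS[j - 1] < s) s = curS[j - 1];
      curD[j] = d; curS[j] = s;
    }
    // candidates: full adapter at any end column, or any prefix at j = n
    bool full = (i == m);
    int jlo = full ? 1 : n, jhi = n;
    if (i >= min_overlap) {
      for (int j = jlo; j <= jhi; ++j) {
        int err = curD[j], len = i;
        if (err > (int)(max_err_frac * len)) continue;
        int score = len - 4 * err;
        int start = curS[j];
        if (score > best_score ||
            (score == best_score && start < best_start)) {
          best_score = score; best_start = start; best_end = j;
          best_err = err; best_len = len;
        }
      }
    }
    std::swap(prevD, curD); std::swap(prevS, curS);
  }
  if (best_start < 0) return none;
  return IntegerVector::create(best_start, best_end, best_err, best_len);
}
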