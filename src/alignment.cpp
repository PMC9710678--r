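#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

// Global (Needleman-Wunsch) alignment score with match = +1, mismatch = 0,
// gap = -1 per inserted/deleted position. The score is the number of
// identical aligned positions net of the gap penalty; it equals the raw
// identity count whenever the optimal alignment is ungapped. Two rolling
// rows, O(min) memory.
// [[Rcpp::export]]
int nw_score_cpp(const std::string& a, const std::string& b,
                 double match = 1.0, double mismatch = 0.0, double gap = -1.0) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = gap * i;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      cur[j] = std::max(diag, std::max(prev[j] + gap, cur[j - 1] + gap));
    }
    std::swap(prev, cur);
  }
  return (int)std::lround(prev[m]);
}
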