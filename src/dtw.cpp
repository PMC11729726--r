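#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Classic exact DTW with steps {(1,0),(0,1),(1,1)}, rolling-row dynamic
// program so long squiggle pairs stay in O(min-row) memory. A companion
// path-length table is carried along so no full backtrack matrix is needed.
// [[Rcpp::export]]
List dtw_cpp(NumericVector x, NumericVector y, bool squared) {
  const R_xlen_t n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input signal");
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  std::vector<int> plen_prev(m + 1, 0), plen_cur(m + 1, 0);
  prev[0] = 0.0;

  for (R_xlen_t i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (R_xlen_t j = 1; j <= m; ++j) {
      double d = x[i - 1] - y[j - 1];
      double c = squared ? d * d : std::fabs(d);
      // tie preference: diagonal, then vertical, then horizontal
      double best = prev[j - 1];
      int bl = plen_prev[j - 1];
      if (prev[j] < best) { best = prev[j]; bl = plen_prev[j]; }
      if (cur[j - 1] < best) { best = cur[j - 1]; bl = plen_cur[j - 1]; }
      cur[j] = c + best;
      plen_cur[j] = bl + 1;
    }
    std::swap(prev, cur);
    std::swap(plen_prev, plen_cur);
    std::fill(cur.begin(), cur.end(), inf);
  }
  return List::create(_["cost"] = prev[m], _["path_len"] = plen_prev[m]);
}
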