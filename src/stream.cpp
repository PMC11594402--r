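#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Streaming loops for the two median estimators.  Both maintain an
// always-sorted vector; complexity per sample is O(log L) for the search plus
// O(L) element moves, which is fast enough at electrophysiology rates.

static inline void check_L(int L) {
  if (L < 3 || L % 2 == 0)
    stop("buffer length L must be an odd integer >= 3, got %d", L);
}

static inline void check_finite(double x, R_xlen_t i) {
  if (!R_finite(x))
    stop("non-finite sample at position %d", (int)(i + 1));
}

// Warm-up estimate: middle element of the sorted partial buffer, lower middle
// when the count is even.
static inline double partial_estimate(const std::vector<double>& buf) {
  size_t k = buf.size();
  return (k % 2 == 1) ? buf[k / 2] : buf[k / 2 - 1];
}

// Memory-less streaming median (NM).  The buffer is always sorted; a sample
// below the central value is inserted on the left and the maximum dropped, a
// sample above is inserted on the right and the minimum dropped; a sample
// exactly equal to the central value lands at the centre and the tie bit S
// decides which extreme goes.  Insertion is after any equal values
// (upper-bound), mirroring the hardware comparator C_i = [R_i > X].
//
// snapshot_at: strictly increasing 1-based sample counts (>= L) at which the
// full buffer contents are copied out (for density-dynamics experiments).
// [[Rcpp::export]]
List nm_filter_cpp(NumericVector x, int L, bool random_tie = false,
                   IntegerVector snapshot_at = IntegerVector(0),
                   Nullable<NumericVector> init = R_NilValue,
                   int init_toggle = 0) {
  check_L(L);
  R_xlen_t n = x.size();
  int m = L / 2;
  std::vector<double> buf;
  buf.reserve(L + 1);
  int toggle = init_toggle ? 1 : 0;
  if (init.isNotNull()) {
    NumericVector b(init);
    if ((int)b.size() != L) stop("init buffer must have exactly L elements");
    for (int i = 0; i < L; ++i) {
      check_finite(b[i], i);
      if (i > 0 && b[i] < b[i - 1]) stop("init buffer must be sorted");
      buf.push_back(b[i]);
    }
  }
  NumericVector est(n);
  NumericMatrix snaps(L, snapshot_at.size());
  int si = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    check_finite(xi, i);
    if ((int)buf.size() < L) {
      buf.insert(std::upper_bound(buf.begin(), buf.end(), xi), xi);
      est[i] = partial_estimate(buf);
    } else {
      double M = buf[m];
      if (xi < M) {
        buf.pop_back();
        buf.insert(std::upper_bound(buf.begin(), buf.end(), xi), xi);
      } else if (xi > M) {
        buf.erase(buf.begin());
        buf.insert(std::upper_bound(buf.begin(), buf.end(), xi), xi);
      } else {
        int drop_first;
        if (random_tie) {
          drop_first = (unif_rand() < 0.5) ? 1 : 0;
        } else {
          drop_first = toggle;
          toggle = 1 - toggle;
        }
        if (drop_first) buf.erase(buf.begin());
        else buf.pop_back();
        buf.insert(buf.begin() + m, xi);
      }
      est[i] = buf[m];
    }
    while (si < snapshot_at.size() && snapshot_at[si] == (int)(i + 1)) {
      if ((int)buf.size() < L)
        stop("snapshot requested before the buffer is full");
      for (int r = 0; r < L; ++r) snaps(r, si) = buf[r];
      ++si;
    }
  }
  return List::create(_["estimates"] = est,
                      _["buffer"] = NumericVector(buf.begin(), buf.end()),
                      _["tie_toggle"] = toggle,
                      _["snapshots"] = snaps);
}

// Classical moving median (CMM): exact median of the last L samples.  A deque
// keeps arrival order for eviction; a parallel sorted vector answers the
// median query.  Evicting any one instance of the oldest value leaves the
// window multiset identical, so lower_bound suffices.
// [[Rcpp::export]]
NumericVector cmm_filter_cpp(NumericVector x, int L) {
  check_L(L);
  R_xlen_t n = x.size();
  std::deque<double> window;
  std::vector<double> buf;
  buf.reserve(L + 1);
  NumericVector est(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    check_finite(xi, i);
    if ((int)window.size() == L) {
      double old = window.front();
      window.pop_front();
      buf.erase(std::lower_bound(buf.begin(), buf.end(), old));
    }
    window.push_back(xi);
    buf.insert(std::upper_bound(buf.begin(), buf.end(), xi), xi);
    est[i] = partial_estimate(buf);
  }
  return est;
}
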