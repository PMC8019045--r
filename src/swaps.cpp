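#include <Rcpp.h>
using namespace Rcpp;

// Sequential data-stream swaps on a scan-by-unit presence matrix.
//
// One attempted swap: pick two non-focal associate placements (scan, unit)
// uniformly at random; if they involve two different scans (the same day
// when same_day is true) and two different units, and neither unit already
// occurs in the other scan's presence set, exchange them (a checkerboard
// swap). This preserves every scan's presence-set size and every unit's
// total sighting count; focal units never leave their own scans.
//
// The number of non-focal placements is itself invariant under the swap, so
// proposing uniform placement pairs gives a symmetric transition kernel and
// the chain's stationary distribution is uniform over the reachable
// margin-preserving datasets.
//
// X is modified in place (the caller owns the copy). Returns the number of
// accepted swaps (== n_accept unless the attempt budget ran out).

// [[Rcpp::export]]
int cpp_stream_swaps(IntegerMatrix X, IntegerVector focal, IntegerVector day,
                     int n_accept, bool same_day, double max_tries) {
  int n_scans = X.nrow();
  int n_units = X.ncol();
  if (n_scans < 2 || n_units < 2) return 0;

  // index of non-focal associate placements
  std::vector<int> pscan, punit;
  for (int s = 0; s < n_scans; ++s)
    for (int u = 0; u < n_units; ++u)
      if (X(s, u) == 1 && u != focal[s]) {
        pscan.push_back(s);
        punit.push_back(u);
      }
  int m = (int)pscan.size();
  if (m < 2) return 0;

  int accepted = 0;
  double tries = 0;
  while (accepted < n_accept && tries < max_tries) {
    ++tries;
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i == j) continue;
    int s1 = pscan[i], a = punit[i];
    int s2 = pscan[j], b = punit[j];
    if (s1 == s2 || a == b) continue;
    if (same_day && day[s1] != day[s2]) continue;
    // target scans must not already contain the incoming unit (including
    // as focal)
    if (X(s2, a) == 1 || a == focal[s2]) continue;
    if (X(s1, b) == 1 || b == focal[s1]) continue;

    X(s1, a) = 0;
    X(s2, a) = 1;
    X(s2, b) = 0;
    X(s1, b) = 1;
    pscan[i] = s2;  // placement of a moved to s2
    pscan[j] = s1;  // placement of b moved to s1
    ++accepted;
  }
  return accepted;
}
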