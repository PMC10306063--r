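#include <Rcpp.h>
using namespace Rcpp;

// Exact lattice convolution of per-position score distributions.
//
// bins: L x A integer matrix; bins(i, a) is the lattice index (score value
//       floor-divided by the grid step) of letter a's log-odds score at
//       window position i.
// q:    background probability of each letter (length A).
// trunc_tail: cumulative mass trimmed from each end after every convolution
//       step (keeps the support compact; the removed mass is negligible).
//
// Returns the distribution of the window score under an i.i.d. background
// sequence as a list: offset (lattice index of mass[0]) and mass.
// [[Rcpp::export]]
List cpp_null_convolve(IntegerMatrix bins, NumericVector q,
                       double trunc_tail = 1e-12) {
  const int L = bins.nrow(), A = bins.ncol();
  if (q.size() != A) stop("q length must match bins columns");

  std::vector<double> cur(1, 1.0);
  long off = 0;

  for (int i = 0; i < L; ++i) {
    int kmin = bins(i, 0), kmax = bins(i, 0);
    for (int a = 1; a < A; ++a) {
      if (bins(i, a) < kmin) kmin = bins(i, a);
      if (bins(i, a) > kmax) kmax = bins(i, a);
    }
    const size_t n_new = cur.size() + (size_t)(kmax - kmin);
    std::vector<double> nxt(n_new, 0.0);
    for (int a = 0; a < A; ++a) {
      const double qa = q[a];
      if (qa <= 0.0) continue;
      const int shift = bins(i, a) - kmin;
      const size_t n = cur.size();
      for (size_t k = 0; k < n; ++k) nxt[k + shift] += qa * cur[k];
    }
    off += kmin;
    // trim negligible tails to keep the support compact
    size_t lo = 0, hi = nxt.size();
    double acc = 0.0;
    while (lo < hi && acc + nxt[lo] < trunc_tail) acc += nxt[lo++];
    acc = 0.0;
    while (hi > lo && acc + nxt[hi - 1] < trunc_tail) acc += nxt[--hi];
    cur.assign(nxt.begin() + lo, nxt.begin() + hi);
    off += (long)lo;
  }

  return List::create(_["offset"] = (double)off,
                      _["mass"] = NumericVector(cur.begin(), cur.end()));
}
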