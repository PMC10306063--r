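#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Order-invariant cache key of a window's binned score atoms: the null
// convolution is invariant to permuting letters within a position and to
// permuting positions, so rows are sorted, then rows ordered, then hashed
// (two FNV-1a streams; 128 bits makes collisions negligible).
// [[Rcpp::export]]
std::string cpp_bins_key(IntegerMatrix bins) {
  const int L = bins.nrow(), A = bins.ncol();
  std::vector<std::vector<int>> rows(L, std::vector<int>(A));
  for (int i = 0; i < L; ++i) {
    for (int a = 0; a < A; ++a) rows[i][a] = bins(i, a);
    std::sort(rows[i].begin(), rows[i].end());
  }
  std::sort(rows.begin(), rows.end());
  uint64_t h1 = 1469598103934665603ULL, h2 = 1099511628211ULL ^ 0x9e3779b9ULL;
  auto mix = [&](uint64_t v) {
    h1 ^= v; h1 *= 1099511628211ULL;
    h2 ^= (v * 0x9e3779b97f4a7c15ULL) ^ (h2 >> 29); h2 *= 0xbf58476d1ce4e5b9ULL;
  };
  mix((uint64_t)L); mix((uint64_t)A);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < A; ++a) mix((uint64_t)(int64_t)rows[i][a] + (1ULL << 40));
  char buf[36];
  snprintf(buf, sizeof(buf), "%016llx%016llx",
           (unsigned long long)h1, (unsigned long long)h2);
  return std::string(buf);
}
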