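#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov base-pair maximization with a minimum hairpin loop of `min_loop`
// unpaired bases. Canonical pairs only (AU, GC, GU and reverses); T is U.
// Returns the maximum number of pairs.
// [[Rcpp::export(name = ".nussinov_pairs")]]
int nussinov_pairs(std::string seq, int min_loop = 3) {
  const int n = seq.size();
  if (n < min_loop + 2) return 0;
  // encode: A=0, C=1, G=2, U/T=3, other=4
  std::vector<unsigned char> b(n, 4);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': b[i] = 0; break;
      case 'C': b[i] = 1; break;
      case 'G': b[i] = 2; break;
      case 'T': case 'U': b[i] = 3; break;
    }
  }
  static const bool pairable[5][5] = {
    // A      C      G      U      N
    {false, false, false, true,  false},   // A
    {false, false, true,  false, false},   // C
    {false, true,  false, true,  false},   // G
    {true,  false, true,  false, false},   // U
    {false, false, false, false, false}};  // N
  std::vector<int> dp(n * n, 0);  // dp[i*n + j]
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int *row_i1 = &dp[(i + 1) * n];
      int best = row_i1[j];  // i unpaired
      const unsigned char bi = b[i];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (pairable[bi][b[k]]) {
          int v = 1 + (k > i + 1 ? row_i1[k - 1] : 0) +
                  (k < j ? dp[(k + 1) * n + j] : 0);
          if (v > best) best = v;
        }
      }
      dp[i * n + j] = best;
    }
  }
  return dp[n - 1];
}
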