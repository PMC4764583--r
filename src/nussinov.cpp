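#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style dynamic program) used as a fast
// folding proxy. Pairs allowed: Watson-Crick (AU/AT, GC) and wobble GU/GT.
// minloop enforces a minimum hairpin loop (unpaired nucleotides between a
// pair), default 3.

static inline bool can_pair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

static int max_pairs_dp(const std::string &s, int minloop) {
  int n = s.size();
  if (n < 2) return 0;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];                       // i unpaired
      for (int k = i + minloop + 1; k <= j; ++k) {  // i pairs with k
        if (can_pair(s[i], s[k])) {
          int left = (k > i + 1) ? M[i + 1][k - 1] : 0;
          int right = (k < j) ? M[k + 1][j] : 0;
          int v = 1 + left + right;
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}

// [[Rcpp::export(name = ".nussinov_max_pairs")]]
int nussinov_max_pairs(std::string seq, int minloop = 3) {
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = toupper(seq[i]);
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'U')
      stop("non-nucleotide character in sequence");
    seq[i] = c;
  }
  return max_pairs_dp(seq, minloop);
}

// Sliding-window maximum pair counts, step 1. Windows longer than the
// sequence collapse to a single whole-sequence window.
// [[Rcpp::export(name = ".nussinov_windows")]]
IntegerVector nussinov_windows(std::string seq, int window, int minloop = 3) {
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = toupper(seq[i]);
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'U')
      stop("non-nucleotide character in sequence");
    seq[i] = c;
  }
  int n = seq.size();
  if (n <= window) {
    IntegerVector out(1);
    out[0] = max_pairs_dp(seq, minloop);
    return out;
  }
  int nw = n - window + 1;
  IntegerVector out(nw);
  for (int i = 0; i < nw; ++i)
    out[i] = max_pairs_dp(seq.substr(i, window), minloop);
  return out;
}
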