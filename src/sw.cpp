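#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Best local alignment score with affine gaps. Gap of length g costs
// gap_open + (g - 1) * gap_extend (SSW convention: the opening base already
// pays gap_open). 'N' never matches anything, including another 'N'.
static int sw_one(const std::string &a, const std::string &b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> H(m + 1, 0), E(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;       // H[i-1][j-1]
    int F = 0;          // gap in b (vertical)
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int up = H[j];
      E[j] = std::max(H[j] - gap_open, E[j] - gap_extend);
      F = std::max(H[j - 1] - gap_open, F - gap_extend);
      const bool is_match = (ai == b[j - 1]) && ai != 'N';
      int h = diag + (is_match ? match : -mismatch);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0);
      H[j] = h;
      diag = up;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_pair")]]
int sw_score_pair(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  return sw_one(a, b, match, mismatch, gap_open, gap_extend);
}

// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(CharacterVector reads, CharacterVector refs,
                              int match, int mismatch, int gap_open,
                              int gap_extend) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> ref_s(nf);
  for (int j = 0; j < nf; ++j) ref_s[j] = as<std::string>(refs[j]);
  IntegerMatrix out(nr, nf);
  for (int i = 0; i < nr; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    for (int j = 0; j < nf; ++j) {
      out(i, j) = sw_one(rd, ref_s[j], match, mismatch, gap_open, gap_extend);
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
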