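#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with a linear gap penalty.
//
// Identity downstream is computed over aligned columns (gap columns count);
// 'N' never scores as a match, so unsequenced bases cannot inflate identity.
// Tie-breaking is deterministic: the first maximal cell in row-major order
// wins, and traceback prefers diagonal over up over left.
//
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s,
                  int match = 2, int mismatch = -3, int gap = -5) {
  const int n = (int) q.size();
  const int m = (int) s.size();
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  const int W = m + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    const int *prev = &H[(size_t)(i - 1) * W];
    int *cur = &H[(size_t)i * W];
    for (int j = 1; j <= m; ++j) {
      const char sc = s[j - 1];
      const int sub = (qc == sc && qc != 'N') ? match : mismatch;
      int h = prev[j - 1] + sub;
      const int up = prev[j] + gap;
      const int left = cur[j - 1] + gap;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, sa;
  int i = bi, j = bj, matches = 0, cols = 0, gaps = 0;
  while (i > 0 && j > 0) {
    const int h = H[(size_t)i * W + j];
    if (h == 0) break;
    const int sub = (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ? match : mismatch;
    if (h == H[(size_t)(i - 1) * W + (j - 1)] + sub) {
      qa += q[i - 1]; sa += s[j - 1];
      if (sub == match) ++matches;
      ++cols; --i; --j;
    } else if (h == H[(size_t)(i - 1) * W + j] + gap) {
      qa += q[i - 1]; sa += '-'; ++cols; ++gaps; --i;
    } else {
      qa += '-'; sa += s[j - 1]; ++cols; ++gaps; --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["matches"] = matches, _["columns"] = cols, _["gaps"] = gaps,
    _["q_aln"] = qa, _["s_aln"] = sa);
}
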