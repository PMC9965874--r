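#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global end-to-end alignment with fixed scoring: match +1, mismatch 0,
// gap -1 (linear, no distinct opening penalty). Traceback ties are resolved
// deterministically: diagonal (match/mismatch) over a gap in `a` (consuming
// a character of `b`) over a gap in `b`. Identity is the fraction of
// identical columns over the full alignment length, gap columns included in
// the denominator. Memory: two rolling score rows plus a byte per cell for
// the traceback.
// [[Rcpp::export]]
List align_identity_cpp(std::string a, std::string b) {
  const long la = (long)a.size(), lb = (long)b.size();
  if (la == 0 || lb == 0) stop("align_identity: empty sequence");
  const int GAP = -1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  // 0 = diagonal, 1 = gap in a (move left), 2 = gap in b (move up)
  std::vector<unsigned char> ptr((size_t)(la + 1) * (lb + 1));
  for (long j = 0; j <= lb; ++j) { prev[j] = (int)(-j); ptr[j] = 1; }
  ptr[0] = 0;
  for (long i = 1; i <= la; ++i) {
    cur[0] = (int)(-i);
    ptr[(size_t)i * (lb + 1)] = 2;
    const char ai = a[i - 1];
    for (long j = 1; j <= lb; ++j) {
      int sdiag = prev[j - 1] + (ai == b[j - 1] ? 1 : 0);
      int sleft = cur[j - 1] + GAP;
      int sup   = prev[j] + GAP;
      int best = sdiag; unsigned char p = 0;
      if (sleft > best) { best = sleft; p = 1; }
      if (sup   > best) { best = sup;   p = 2; }
      cur[j] = best;
      ptr[(size_t)i * (lb + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  const int score = prev[lb];
  long i = la, j = lb, matches = 0, len = 0;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[(size_t)i * (lb + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (j > 0 && p == 1) {
      --j;
    } else {
      --i;
    }
    ++len;
  }
  return List::create(_["identity_pct"] = 100.0 * (double)matches / (double)len,
                      _["matches"] = (double)matches,
                      _["alignment_length"] = (double)len,
                      _["score"] = (double)score);
}

// Score-only variant of the same alignment (two rolling rows, no traceback).
// Used to bound identity cheaply: along any optimal-score path,
// matches = score + gaps and alignment length = (la + lb + gaps) / 2, so
// identity is increasing in the gap count, which cannot exceed
// min(la, lb) - score. The resulting bound is exact, never an estimate.
// [[Rcpp::export]]
double align_score_cpp(std::string a, std::string b) {
  const long la = (long)a.size(), lb = (long)b.size();
  if (la == 0 || lb == 0) stop("align_score: empty sequence");
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (long j = 0; j <= lb; ++j) prev[j] = (int)(-j);
  for (long i = 1; i <= la; ++i) {
    cur[0] = (int)(-i);
    const char ai = a[i - 1];
    const int *pr = prev.data();
    int *cu = cur.data();
    for (long j = 1; j <= lb; ++j) {
      int best = pr[j - 1] + (ai == b[j - 1] ? 1 : 0);
      const int sleft = cu[j - 1] - 1;
      if (sleft > best) best = sleft;
      const int sup = pr[j] - 1;
      if (sup > best) best = sup;
      cu[j] = best;
    }
    std::swap(prev, cur);
  }
  return (double)prev[lb];
}
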