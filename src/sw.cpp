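#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.  A gap of length L costs
// gap_open + L * gap_extend (open-plus-extend convention).  Sequences are
// 1-based integer codes into the score matrix.
static int sw_core(const int* a, int m, const int* b, int n,
                   const IntegerMatrix& S, int gap_open, int gap_extend) {
  const int NEG = INT_MIN / 4;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      E = std::max(Hcur[j - 1] - gap_open - gap_extend, E - gap_extend);
      F[j] = std::max(Hprev[j] - gap_open - gap_extend, F[j] - gap_extend);
      int h = Hprev[j - 1] + S(ai, b[j - 1] - 1);
      h = std::max(h, E);
      h = std::max(h, F[j]);
      h = std::max(h, 0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// [[Rcpp::export]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                 int gap_open, int gap_extend) {
  if (a.size() == 0 || b.size() == 0) return 0;
  return sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                 S, gap_open, gap_extend);
}

// Batch scoring for a search: seqs is a list of encoded integer vectors,
// (qidx, tidx) are 1-based indices of the pairs to align.
// [[Rcpp::export]]
IntegerVector sw_search_cpp(List seqs, IntegerVector qidx, IntegerVector tidx,
                            IntegerMatrix S, int gap_open, int gap_extend) {
  int npair = qidx.size();
  IntegerVector out(npair);
  std::vector<IntegerVector> enc(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) enc[i] = seqs[i];
  for (int p = 0; p < npair; ++p) {
    const IntegerVector& a = enc[qidx[p] - 1];
    const IntegerVector& b = enc[tidx[p] - 1];
    if (a.size() == 0 || b.size() == 0) {
      out[p] = 0;
    } else {
      out[p] = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       S, gap_open, gap_extend);
    }
  }
  return out;
}
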