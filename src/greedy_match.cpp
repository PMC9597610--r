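#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Greedy variable-ratio caliper matching core.
//
// Candidates arrive sorted by (logit, id) ascending. Matching proceeds in
// rounds 1..max_ratio; in round r base subjects are visited in the order
// given by column r of round_orders (1-based base indices). Each base
// subject is paired with its nearest still-unmatched candidate within the
// caliper; exact-distance ties are broken by the lowest candidate id. Base
// subjects with no match after round 1 take no further part. A removed
// candidate is spliced out of a doubly linked list over the sorted order,
// so nearest-neighbour lookups stay cheap.
//
// Returns an nb x max_ratio matrix of matched candidate ids (0 = none).
// [[Rcpp::export]]
IntegerMatrix greedy_match_core(NumericVector base_logit,
                                NumericVector cand_logit,
                                IntegerVector cand_id,
                                double caliper,
                                int max_ratio,
                                IntegerMatrix round_orders) {
  const int nb = base_logit.size();
  const int m = cand_logit.size();
  std::vector<int> prev(m + 2), nxt(m + 2);
  std::vector<char> alive(m + 2, 0);
  for (int i = 0; i <= m + 1; ++i) { prev[i] = i - 1; nxt[i] = i + 1; }
  for (int i = 1; i <= m; ++i) alive[i] = 1;

  IntegerMatrix out(nb, max_ratio);
  std::fill(out.begin(), out.end(), 0);
  std::vector<int> nmatched(nb, 0);

  // last sorted index (1-based) with logit <= base logit; 0 if none
  std::vector<int> pos(nb);
  for (int b = 0; b < nb; ++b)
    pos[b] = std::upper_bound(cand_logit.begin(), cand_logit.end(),
                              base_logit[b]) - cand_logit.begin();

  int remaining = m;
  for (int r = 0; r < max_ratio && remaining > 0; ++r) {
    for (int k = 0; k < nb; ++k) {
      int b = round_orders(k, r) - 1;
      if (r > 0 && nmatched[b] == 0) continue;  // dropped after round 1
      int li = pos[b];
      while (li >= 1 && !alive[li]) li = prev[li];
      int ri = pos[b] + 1;
      while (ri <= m && !alive[ri]) ri = nxt[ri];
      double dl = (li >= 1) ? base_logit[b] - cand_logit[li - 1] : R_PosInf;
      double dr = (ri <= m) ? cand_logit[ri - 1] - base_logit[b] : R_PosInf;
      if (dl > caliper && dr > caliper) continue;
      // Ties break to the lowest candidate id. Within an equal-logit run,
      // ids ascend with the sorted index, so the lowest-id alive candidate
      // at distance dl is the leftmost alive element of the left run, and
      // at distance dr it is ri itself (the first alive of the right run).
      int chosen;
      if (dr < dl) chosen = ri;
      else {
        int bestL = li;
        int j = prev[li];
        while (j >= 1) {
          while (j >= 1 && !alive[j]) j = prev[j];
          if (j >= 1 && cand_logit[j - 1] == cand_logit[li - 1]) {
            bestL = j; j = prev[j];
          } else break;
        }
        if (dl < dr) chosen = bestL;
        else {
          int idL = cand_id[bestL - 1];
          int idR = (ri <= m) ? cand_id[ri - 1] : INT_MAX;
          chosen = (idL <= idR) ? bestL : ri;
        }
      }
      alive[chosen] = 0;
      nxt[prev[chosen]] = nxt[chosen];
      prev[nxt[chosen]] = prev[chosen];
      --remaining;
      out(b, nmatched[b]) = cand_id[chosen - 1];
      ++nmatched[b];
      if (remaining == 0) break;
    }
  }
  return out;
}
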