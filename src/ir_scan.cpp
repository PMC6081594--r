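#include <Rcpp.h>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, anything else (N) = 4.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

// Watson-Crick pairing; N never pairs.
static inline bool wc(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}

// Enumerate per-center maximal inverted-repeat candidates.
//
// A center is a gap position g (0-based index of the first base after the
// left arm) plus a spacer length sp; the spacer occupies [g, g+sp), the left
// arm ends at g-1 and the right arm starts at g+sp.  Pair k (k = 1 is the
// innermost pair, adjacent to the spacer) matches position g-k against
// g+sp+k-1.  A hit with arm length a is valid when the innermost pair (k=1)
// and the outermost pair (k=a) are exact Watson-Crick matches and the
// interior pairs (k = 2..a-1) carry at most max_mismatch mismatches.  For
// each center the largest valid arm within [min_arm, max_arm] is emitted;
// interior mismatches only accumulate, so the scan can stop as soon as the
// interior budget is exceeded.
// [[Rcpp::export]]
DataFrame cpp_scan_candidates(std::string seq, int min_arm, int max_arm,
                              int max_spacer, int max_mismatch) {
  const int n = (int) seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::vector<int> out_start, out_arm, out_sp, out_mm;
  for (int g = 1; g < n; ++g) {
    for (int sp = 0; sp <= max_spacer; ++sp) {
      const int r0 = g + sp;              // innermost right-arm position
      if (r0 >= n) break;
      if (!wc(code[g - 1], code[r0])) continue;
      int interior = 0;                   // mismatches among pairs 2..a-1
      int best_a = -1, best_mm = 0;
      for (int a = 1; a <= max_arm; ++a) {
        const int p = g - a, q = r0 + a - 1;
        if (p < 0 || q >= n) break;
        const bool mism = !wc(code[p], code[q]);
        if (!mism && a >= min_arm && interior <= max_mismatch) {
          best_a = a;
          best_mm = interior;
        }
        if (a >= 2 && mism) {
          if (++interior > max_mismatch) break;
        }
      }
      if (best_a >= min_arm) {
        out_start.push_back(g - best_a);
        out_arm.push_back(best_a);
        out_sp.push_back(sp);
        out_mm.push_back(best_mm);
      }
    }
  }
  return DataFrame::create(_["left_start"] = out_start,
                           _["arm_len"]    = out_arm,
                           _["spacer_len"] = out_sp,
                           _["mismatches"] = out_mm);
}
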