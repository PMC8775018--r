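// Wraparound affine-gap local alignment of a read against an unbounded
// tandem concatenation of a short motif.
//
// DP layout: rows i = 0..n index read prefixes; columns j = 0..m-1 index the
// motif position of the last reference base consumed.  The diagonal and
// horizontal predecessors of column j live in column (j-1) mod m, so the
// reference is effectively motif^inf without ever materialising it.
//
// Each DP state carries a lexicographic value (score max; read start min;
// deletions min; insertions min; substitutions min), all additive along
// alignment edges, so the optimum is a well-defined function of the set of
// candidate local alignments rather than of the DP graph layout.  This makes
// the result exactly reproducible by any other correct affine-gap aligner
// over the same alignment set (in particular plain Smith-Waterman against an
// explicitly tiled reference) and pins down the interruption counts even
// when several co-optimal paths exist.  No traceback is needed: counts and
// start position ride along in the state.
//
// The horizontal (reference-consuming) recurrence runs within a row and can
// wrap past the j = 0 boundary.  Because gap_extend >= 1, any alignment
// consuming a full motif period within one row is strictly score-dominated
// (drop m deletions, gain m*gap_extend), so an optimal within-row segment
// spans fewer than m columns and wraps the boundary at most once: two sweeps
// per row reach the fixed point.

#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct St {
  int sc, st, del, ins, sub;
};

inline bool better(const St& a, const St& b) {
  if (a.sc != b.sc) return a.sc > b.sc;
  if (a.st != b.st) return a.st < b.st;
  if (a.del != b.del) return a.del < b.del;
  if (a.ins != b.ins) return a.ins < b.ins;
  return a.sub < b.sub;
}

inline bool valid(const St& a) { return a.sc > NEG / 2; }

}  // namespace

// [[Rcpp::export(name = ".wrap_align_cpp")]]
List wrap_align_cpp(std::string read, std::string motif,
                    int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)read.size();
  const int m = (int)motif.size();
  if (n < 1 || m < 1) stop("read and motif must be non-empty");

  const St none = {NEG, 0, 0, 0, 0};
  std::vector<St> H((size_t)(n + 1) * m, none);
  std::vector<St> D((size_t)(n + 1) * m, none);
  std::vector<St> I((size_t)(n + 1) * m, none);
  for (int j = 0; j < m; ++j) H[j] = {0, 0, 0, 0, 0};

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * m;
    const size_t prev = (size_t)(i - 1) * m;
    for (int j = 0; j < m; ++j) { H[row + j] = none; D[row + j] = none; }
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < m; ++j) {
        const int jp = (j + m - 1) % m;

        St ins = none;
        {  // vertical: consumes read[i-1] only
          if (valid(H[prev + j])) {
            ins = H[prev + j];
            ins.sc -= gap_open + gap_extend; ins.ins += 1;
          }
          if (valid(I[prev + j])) {
            St e = I[prev + j];
            e.sc -= gap_extend; e.ins += 1;
            if (!valid(ins) || better(e, ins)) ins = e;
          }
        }

        St del = none;
        if (m > 1) {  // horizontal: consumes motif[j] only (wraps in-row)
          if (valid(H[row + jp])) {
            del = H[row + jp];
            del.sc -= gap_open + gap_extend; del.del += 1;
          }
          if (valid(D[row + jp])) {
            St e = D[row + jp];
            e.sc -= gap_extend; e.del += 1;
            if (!valid(del) || better(e, del)) del = e;
          }
        }
        // m == 1: a read-gap consumes a whole period, always score-dominated

        St h = {0, i, 0, 0, 0};  // fresh local start at read offset i
        if (valid(H[prev + jp])) {  // diagonal
          St d = H[prev + jp];
          if (read[i - 1] == motif[j]) d.sc += match;
          else { d.sc -= mismatch; d.sub += 1; }
          if (better(d, h)) h = d;
        }
        if (valid(del) && better(del, h)) h = del;
        if (valid(ins) && better(ins, h)) h = ins;

        H[row + j] = h;
        D[row + j] = del;
        I[row + j] = ins;
      }
    }
  }

  // best end cell: highest score, then smallest read start, then shortest
  // span, then canonical counts (fewest deletions, insertions,
  // substitutions), then smallest column
  bool have = false;
  St sel = none; int sel_end = 0, sel_j = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j < m; ++j) {
      const St& h = H[(size_t)i * m + j];
      if (h.sc <= 0) continue;
      bool take = false;
      if (!have) take = true;
      else if (h.sc != sel.sc) take = h.sc > sel.sc;
      else if (h.st != sel.st) take = h.st < sel.st;
      else if (i - h.st != sel_end - sel.st) take = i - h.st < sel_end - sel.st;
      else if (h.del != sel.del) take = h.del < sel.del;
      else if (h.ins != sel.ins) take = h.ins < sel.ins;
      else if (h.sub != sel.sub) take = h.sub < sel.sub;
      else take = j < sel_j;
      if (take) { sel = h; sel_end = i; sel_j = j; have = true; }
    }
  }
  if (!have) return List::create(_["found"] = false);

  const int span = sel_end - sel.st;
  const int mat = span - sel.sub - sel.ins;
  return List::create(
    _["found"] = true,
    _["score"] = sel.sc,
    _["start"] = sel.st,
    _["end"] = sel_end,
    _["matches"] = mat,
    _["substitutions"] = sel.sub,
    _["insertions"] = sel.ins,
    _["deletions"] = sel.del);
}
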