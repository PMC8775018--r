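// Reference implementation: plain full-matrix affine-gap Smith-Waterman of a
// read against an explicit (finite) reference string, e.g. a tiling of a
// repeat motif.  Deliberately straightforward -- dense (n+1) x (L+1) state
// matrices -- so it can serve as a brute-force check of the wraparound
// aligner.
//
// Optimises the same lexicographic objective as the wraparound DP (score
// max; read start min; deletions min; insertions min; substitutions min) so
// that both implementations select the same alignment value even when
// several paths are co-optimal in score.

#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

const int NEG2 = INT_MIN / 4;

struct NSt {
  int sc, st, del, ins, sub;
};

inline bool nbetter(const NSt& a, const NSt& b) {
  if (a.sc != b.sc) return a.sc > b.sc;
  if (a.st != b.st) return a.st < b.st;
  if (a.del != b.del) return a.del < b.del;
  if (a.ins != b.ins) return a.ins < b.ins;
  return a.sub < b.sub;
}

inline bool nvalid(const NSt& a) { return a.sc > NEG2 / 2; }

}  // namespace

// [[Rcpp::export(name = ".sw_affine_cpp")]]
List sw_affine_cpp(std::string read, std::string ref,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)read.size();
  const int L = (int)ref.size();
  if (n < 1 || L < 1) stop("read and reference must be non-empty");
  const size_t W = (size_t)L + 1;

  const NSt none = {NEG2, 0, 0, 0, 0};
  std::vector<NSt> H((size_t)(n + 1) * W, none);
  std::vector<NSt> D((size_t)(n + 1) * W, none);  // gap in read (consumes ref)
  std::vector<NSt> I((size_t)(n + 1) * W, none);  // gap in ref (consumes read)
  for (int J = 0; J <= L; ++J) H[J] = {0, 0, 0, 0, 0};
  for (int i = 1; i <= n; ++i) H[(size_t)i * W] = {0, i, 0, 0, 0};

  for (int i = 1; i <= n; ++i) {
    for (int J = 1; J <= L; ++J) {
      const size_t c = (size_t)i * W + J;
      const size_t up = c - W;
      const size_t left = c - 1;
      const size_t diagc = up - 1;

      NSt ins = none;
      if (nvalid(H[up])) {
        ins = H[up]; ins.sc -= gap_open + gap_extend; ins.ins += 1;
      }
      if (nvalid(I[up])) {
        NSt e = I[up]; e.sc -= gap_extend; e.ins += 1;
        if (!nvalid(ins) || nbetter(e, ins)) ins = e;
      }

      NSt del = none;
      if (nvalid(H[left])) {
        del = H[left]; del.sc -= gap_open + gap_extend; del.del += 1;
      }
      if (nvalid(D[left])) {
        NSt e = D[left]; e.sc -= gap_extend; e.del += 1;
        if (!nvalid(del) || nbetter(e, del)) del = e;
      }

      NSt h = {0, i, 0, 0, 0};
      if (nvalid(H[diagc])) {
        NSt d = H[diagc];
        if (read[i - 1] == ref[J - 1]) d.sc += match;
        else { d.sc -= mismatch; d.sub += 1; }
        if (nbetter(d, h)) h = d;
      }
      if (nvalid(del) && nbetter(del, h)) h = del;
      if (nvalid(ins) && nbetter(ins, h)) h = ins;

      H[c] = h; D[c] = del; I[c] = ins;
    }
  }

  bool have = false;
  NSt sel = none; int sel_end = 0, sel_J = 0;
  for (int i = 1; i <= n; ++i) {
    for (int J = 1; J <= L; ++J) {
      const NSt& h = H[(size_t)i * W + J];
      if (h.sc <= 0) continue;
      bool take = false;
      if (!have) take = true;
      else if (h.sc != sel.sc) take = h.sc > sel.sc;
      else if (h.st != sel.st) take = h.st < sel.st;
      else if (i - h.st != sel_end - sel.st) take = i - h.st < sel_end - sel.st;
      else if (h.del != sel.del) take = h.del < sel.del;
      else if (h.ins != sel.ins) take = h.ins < sel.ins;
      else if (h.sub != sel.sub) take = h.sub < sel.sub;
      else take = J < sel_J;
      if (take) { sel = h; sel_end = i; sel_J = J; have = true; }
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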