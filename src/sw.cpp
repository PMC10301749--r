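#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (a gap of length L costs
// gap_open + L * gap_ext, the BLAST convention) and full traceback.
//
// ref/tgt are 1-based integer encodings into the rows/cols of `sub`.
// Returns the optimal local alignment: raw score, 0-based half-open spans on
// both sequences, the number of identical aligned residue pairs and the total
// number of alignment columns (gap columns included). Score ties are broken
// toward the earliest (reference, target) end coordinate, which is
// deterministic for any input.
//
// Traceback state is one byte per cell:
//   bits 0-1: H origin (0 = stop, 1 = diagonal, 2 = E, 3 = F)
//   bit 2   : E extended from E (else opened from H)
//   bit 3   : F extended from F (else opened from H)
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector ref, IntegerVector tgt, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int m = ref.size(), n = tgt.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  if ((double)m * (double)n > 1.6e9)
    stop("alignment problem too large (%d x %d)", m, n);

  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_ext;  // cost of the first gap residue
  const int nsub = sub.nrow();
  const int* refp = INTEGER(ref);
  const int* tgtp = INTEGER(tgt);
  for (int i = 0; i < m; ++i)
    if (refp[i] < 1 || refp[i] > nsub) stop("reference residue code out of range");
  for (int j = 0; j < n; ++j)
    if (tgtp[j] < 1 || tgtp[j] > nsub) stop("target residue code out of range");

  // row-major copy of the (column-major R) substitution matrix, and
  // 0-based target codes, for a tight inner loop
  std::vector<int> subT((size_t)nsub * nsub);
  const int* subp = INTEGER(sub);
  for (int r = 0; r < nsub; ++r)
    for (int c = 0; c < nsub; ++c)
      subT[(size_t)r * nsub + c] = subp[r + (size_t)c * nsub];
  std::vector<int> t0(n);
  for (int j = 0; j < n; ++j) t0[j] = tgtp[j] - 1;

  std::vector<uint8_t> tb((size_t)m * n, 0);
  std::vector<int> Hbuf(2 * (n + 1), 0), Fvec(n + 1, NEG);

  int best = 0, besti = 0, bestj = 0;
  int* Hprev = Hbuf.data();
  int* Hcur = Hbuf.data() + (n + 1);
  int* Fcol = Fvec.data();
  const int* tj = t0.data();
  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const int* srow = subT.data() + (size_t)(refp[i - 1] - 1) * nsub;
    uint8_t* tbrow = tb.data() + (size_t)(i - 1) * n;
    for (int j = 1; j <= n; ++j) {
      uint8_t cell = 0;
      // E: gap in reference (consumes target)
      int e_open = Hcur[j - 1] - go;
      int e_ext  = E - gap_ext;
      if (e_ext > e_open) { E = e_ext; cell |= 4; } else { E = e_open; }
      // F: gap in target (consumes reference)
      int f_open = Hprev[j] - go;
      int f_ext  = Fcol[j] - gap_ext;
      int F;
      if (f_ext > f_open) { F = f_ext; cell |= 8; } else { F = f_open; }
      Fcol[j] = F;
      // H
      int diag = Hprev[j - 1] + srow[tj[j - 1]];
      int h = 0; uint8_t orig = 0;
      if (diag > h) { h = diag; orig = 1; }
      if (E > h)    { h = E;    orig = 2; }
      if (F > h)    { h = F;    orig = 3; }
      Hcur[j] = h;
      tbrow[j - 1] = cell | orig;
      if (h > best) { best = h; besti = i; bestj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  int i = besti, j = bestj, nmatch = 0, ncols = 0;
  if (best > 0) {
    int state = 0;  // 0 = H, 1 = E, 2 = F
    for (;;) {
      uint8_t cell = tb[(size_t)(i - 1) * n + (j - 1)];
      if (state == 0) {
        uint8_t orig = cell & 3;
        if (orig == 0) break;
        if (orig == 1) {
          ++ncols;
          if (refp[i - 1] == tgtp[j - 1]) ++nmatch;
          --i; --j;
          if (i == 0 || j == 0) break;
        } else if (orig == 2) state = 1;
        else state = 2;
      } else if (state == 1) {          // E consumes target
        ++ncols;
        if (!(cell & 4)) state = 0;
        --j;
        if (j == 0) break;
      } else {                          // F consumes reference
        ++ncols;
        if (!(cell & 8)) state = 0;
        --i;
        if (i == 0) break;
      }
    }
  } else {
    i = 0; j = 0; besti = 0; bestj = 0;
  }

  return List::create(
    _["score"] = best,
    _["ref_start"] = i, _["ref_end"] = besti,
    _["tgt_start"] = j, _["tgt_end"] = bestj,
    _["n_match"] = nmatch, _["n_cols"] = ncols);
}
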