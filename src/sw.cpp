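#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Banded affine-gap Smith-Waterman with full traceback.
//
// Diagonal convention: a cell aligning a[i-1] with b[j-1] (1-based DP indices)
// lies on diagonal d = j - i.  Only cells with band_lo <= d <= band_hi are
// evaluated; passing band_lo = -len(a), band_hi = len(b) gives the exact
// unrestricted DP.  A gap of length k costs gap_open + k * gap_ext (both
// penalties are <= 0).  Characters outside {A,C,G,T} never count as a match;
// the sentinel '#' (used by the caller to mask out previously reported HSPs)
// scores an effectively -Inf so no alignment can cross a masked region.
//
// Returns the single best local alignment: 0-based half-open coordinates in
// both sequences, alignment length in columns, number of identical columns,
// number of gap openings, and the score.

static const double NEG_BIG = -1e12;

static inline double pair_score(char x, char y, double match, double mismatch) {
  if (x == '#' || y == '#') return NEG_BIG;
  if (x == y && (x == 'A' || x == 'C' || x == 'G' || x == 'T')) return match;
  return mismatch;
}

// [[Rcpp::export(name = ".sw_band")]]
List sw_band(std::string a, std::string b,
             double match, double mismatch,
             double gap_open, double gap_ext,
             int band_lo, int band_hi) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band_lo > band_hi) stop("invalid band");
  if (band_lo < -n) band_lo = -n;
  if (band_hi > m) band_hi = m;
  const int width = band_hi - band_lo + 1;
  if ((double)(n + 1) * (double)(width + 2) > 6e8)
    stop("alignment band too large");

  // traceback pointers, one byte per in-band cell:
  //   bits 0-1: H source (0 stop, 1 diagonal, 2 F/up, 3 E/left)
  //   bit 2: E extends an existing gap (else opens from H)
  //   bit 3: F extends an existing gap (else opens from H)
  std::vector<unsigned char> ptr((size_t)(n + 1) * (size_t)(width + 2), 0);
  // rolling rows over j = 0..m; width-indexed access would complicate E
  // (left neighbour is same row) so rows are full-length but only the band
  // is touched; memory is 5 doubles * (m+1).
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG_BIG), Fcur(m + 1, NEG_BIG);
  std::vector<double> Ecur(m + 1, NEG_BIG);

  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int jlo = i + band_lo; if (jlo < 1) jlo = 1;
    int jhi = i + band_hi; if (jhi > m) jhi = m;
    if (jlo > jhi) { // band lies outside this row's columns
      std::swap(Hprev, Hcur);
      std::swap(Fprev, Fcur);
      continue;
    }
    // zero the edges just outside the band on the current row so that
    // in-band cells never read stale values
    Hcur[jlo - 1] = 0.0; Ecur[jlo - 1] = NEG_BIG;
    if (jhi + 1 <= m) { Hcur[jhi + 1] = 0.0; Fcur[jhi + 1] = NEG_BIG; }
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char p = 0;
      // E: gap in a (consumes b[j-1]); left neighbour, current row
      double e_open = Hcur[j - 1] + gap_open + gap_ext;
      double e_ext  = Ecur[j - 1] + gap_ext;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; p |= 4; }
      Ecur[j] = e;
      // F: gap in b (consumes a[i-1]); up neighbour, previous row
      double f_open = Hprev[j] + gap_open + gap_ext;
      double f_ext  = Fprev[j] + gap_ext;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; p |= 8; }
      Fcur[j] = f;
      // H
      double diag = Hprev[j - 1] + pair_score(a[i - 1], b[j - 1], match, mismatch);
      double h = 0.0; unsigned char src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (f > h)    { h = f;    src = 2; }
      if (e > h)    { h = e;    src = 3; }
      Hcur[j] = h;
      p |= src;
      ptr[(size_t)i * (width + 2) + (size_t)(j - (i + band_lo)) + 1] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG_BIG);
    // the band shifts right by one per row; the next row reads Hprev/Fprev
    // only at j-1 and j inside [jlo, jhi+1], and the jhi+1 edge was zeroed
    // before this row's loop, so no stale cell is ever read
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0, _["aln_len"] = 0,
                        _["matches"] = 0, _["gap_opens"] = 0);
  }

  // traceback
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int aln_len = 0, matches = 0, gap_opens = 0;
  int a_end = bi, b_end = bj;
  for (;;) {
    unsigned char p = ptr[(size_t)i * (width + 2) + (size_t)(j - (i + band_lo)) + 1];
    if (state == 0) {
      int src = p & 3;
      if (src == 0) break;
      if (src == 1) {
        ++aln_len;
        if (pair_score(a[i - 1], b[j - 1], 1.0, 0.0) == 1.0) ++matches;
        --i; --j;
      } else if (src == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in a, consume b[j-1]
      ++aln_len;
      bool ext = (p & 4) != 0;
      --j;
      if (!ext) { ++gap_opens; state = 0; }
    } else { // F: gap in b, consume a[i-1]
      ++aln_len;
      bool ext = (p & 8) != 0;
      --i;
      if (!ext) { ++gap_opens; state = 0; }
    }
  }

  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = a_end,
                      _["b_start"] = j, _["b_end"] = b_end,
                      _["aln_len"] = aln_len, _["matches"] = matches,
                      _["gap_opens"] = gap_opens);
}
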