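#include <Rcpp.h>
#include <cctype>
#include <vector>
using namespace Rcpp;

// 4-bit IUPAC encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static inline int base_bits(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_bits(s[i]);
    if (b < 0) stop("non-IUPAC character '%c' at position %d", s[i], (int)(i + 1));
    v[i] = b;
  }
  return v;
}

// A target base matches a primer base when its ambiguity set is a subset of
// the primer's; a target N never matches (suppresses hits in N-runs).
static inline bool iupac_ok(int primer, int target) {
  return target != 15 && (target & ~primer) == 0;
}

// Enumerate every target window to which the primer aligns end-to-end with
// <= n_max mismatches and <= g_max indels.  Feasibility DP: each cell holds a
// bitmask over (mismatches, gaps) pairs still within budget; bit index =
// m * (g_max+1) + g.  Reported counts are the minimal-total (then minimal-gap)
// feasible pair at the final cell.  Coordinates are 1-based inclusive on the
// supplied (already strand-oriented) target string.
// [[Rcpp::export(name = ".primer_window_hits")]]
DataFrame primer_window_hits(std::string target, std::string primer,
                             int n_max, int g_max) {
  std::vector<int> tb = encode(target), pb = encode(primer);
  const int N = (int)tb.size(), L = (int)pb.size();
  const int gw = g_max + 1;
  const int width = (n_max + 1) * gw;
  if (width > 30) stop("edit budgets too large for bitmask DP");
  const unsigned FULL = (width == 32) ? 0xffffffffu : ((1u << width) - 1u);
  // bits whose gap component can still grow
  unsigned KEEPG = 0;
  for (int b = 0; b < width; ++b) if (b % gw < g_max) KEEPG |= (1u << b);
  const int maxW = L + g_max, minW = std::max(1, L - g_max);

  std::vector<int> hs, he, hm, hg;
  std::vector<unsigned> prev(maxW + 1), cur(maxW + 1);

  for (int s = 0; s <= N - minW; ++s) {
    const int wlim = std::min(maxW, N - s);
    // row 0: j target bases consumed by j gaps
    for (int j = 0; j <= wlim; ++j) prev[j] = (j <= g_max) ? (1u << j) : 0u;
    bool alive = true;
    for (int i = 1; i <= L && alive; ++i) {
      alive = false;
      cur[0] = (prev[0] & KEEPG) << 1;  // primer prefix unaligned: gaps
      if (cur[0]) alive = true;
      const int p = pb[i - 1];
      for (int j = 1; j <= wlim; ++j) {
        unsigned diag = prev[j - 1];
        unsigned m = iupac_ok(p, tb[s + j - 1])
                       ? diag
                       : ((diag << gw) & FULL);          // mismatch
        unsigned up   = (prev[j] & KEEPG) << 1;          // gap (primer base)
        unsigned left = (cur[j - 1] & KEEPG) << 1;       // gap (target base)
        cur[j] = m | up | left;
        if (cur[j]) alive = true;
      }
      std::swap(prev, cur);
      if (i == L) {
        for (int j = minW; j <= wlim; ++j) {
          unsigned mask = prev[j];
          if (!mask) continue;
          int bm = -1, bg = -1, bt = 1 << 30;
          for (int t = 0; t <= n_max + g_max && bm < 0; ++t)
            for (int g = 0; g <= std::min(t, g_max); ++g) {
              int mm = t - g;
              if (mm > n_max) continue;
              if (mask & (1u << (mm * gw + g))) { bm = mm; bg = g; bt = t; break; }
            }
          (void)bt;
          hs.push_back(s + 1); he.push_back(s + j);
          hm.push_back(bm); hg.push_back(bg);
        }
      }
    }
  }
  return DataFrame::create(_["start"] = hs, _["end"] = he,
                           _["mismatches"] = hm, _["gaps"] = hg);
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment with affine gaps.  A gap run of length k
// costs gap_open + k * gap_ext.  Pattern (a) bases may be IUPAC-ambiguous and
// match by the subset rule above.  Objective is lexicographic: maximal score,
// then fewest gap columns, then fewest mismatches; end-cell ties resolve to
// the smallest subject then pattern coordinate.  Alignments start and end on
// aligned (substituted) columns, as any flanking gap only lowers the score.

struct Tri { int s, g, m, o; };  // score, gap columns, mismatches, gap opens
static const int NEG = -(1 << 28);

static inline bool better(const Tri& a, const Tri& b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.g != b.g) return a.g < b.g;
  if (a.m != b.m) return a.m < b.m;
  return a.o < b.o;
}
static inline bool same(const Tri& a, const Tri& b) {
  return a.s == b.s && a.g == b.g && a.m == b.m && a.o == b.o;
}

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string a, std::string b, int match, int mismatch,
              int gap_open, int gap_ext) {
  std::vector<int> av = encode(a), bv = encode(b);
  const int la = (int)av.size(), lb = (int)bv.size();
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };
  std::vector<Tri> M((la + 1) * (lb + 1), {NEG, 0, 0, 0});
  std::vector<Tri> Ix(M), Iy(M);  // Ix: gap column consuming a; Iy: consuming b
  const Tri ZERO = {0, 0, 0, 0}, BAD = {NEG, 0, 0, 0};

  Tri best = BAD; int bi = -1, bj = -1;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      bool ok = iupac_ok(av[i - 1], bv[j - 1]);
      Tri d = ZERO;
      const Tri& pm = M[idx(i - 1, j - 1)];
      const Tri& px = Ix[idx(i - 1, j - 1)];
      const Tri& py = Iy[idx(i - 1, j - 1)];
      if (pm.s > NEG && better(pm, d)) d = pm;
      if (px.s > NEG && better(px, d)) d = px;
      if (py.s > NEG && better(py, d)) d = py;
      Tri m = {d.s + (ok ? match : mismatch), d.g, d.m + (ok ? 0 : 1), d.o};
      M[idx(i, j)] = m;

      Tri x = BAD;
      const Tri& um = M[idx(i - 1, j)];
      const Tri& ux = Ix[idx(i - 1, j)];
      const Tri& uy = Iy[idx(i - 1, j)];
      if (um.s > NEG) { Tri c = {um.s + gap_open + gap_ext, um.g + 1, um.m, um.o + 1}; if (better(c, x) || x.s <= NEG) x = c; }
      if (uy.s > NEG) { Tri c = {uy.s + gap_open + gap_ext, uy.g + 1, uy.m, uy.o + 1}; if (x.s <= NEG || better(c, x)) x = c; }
      if (ux.s > NEG) { Tri c = {ux.s + gap_ext, ux.g + 1, ux.m, ux.o}; if (x.s <= NEG || better(c, x)) x = c; }
      Ix[idx(i, j)] = x;

      Tri y = BAD;
      const Tri& lm = M[idx(i, j - 1)];
      const Tri& lx = Ix[idx(i, j - 1)];
      const Tri& ly = Iy[idx(i, j - 1)];
      if (lm.s > NEG) { Tri c = {lm.s + gap_open + gap_ext, lm.g + 1, lm.m, lm.o + 1}; if (better(c, y) || y.s <= NEG) y = c; }
      if (lx.s > NEG) { Tri c = {lx.s + gap_open + gap_ext, lx.g + 1, lx.m, lx.o + 1}; if (y.s <= NEG || better(c, y)) y = c; }
      if (ly.s > NEG) { Tri c = {ly.s + gap_ext, ly.g + 1, ly.m, ly.o}; if (y.s <= NEG || better(c, y)) y = c; }
      Iy[idx(i, j)] = y;

      if (m.s > 0 && (bi < 0 || better(m, best))) { best = m; bi = i; bj = j; }
    }
  }

  if (bi < 0)
    return List::create(_["score"] = 0);

  // traceback from (bi,bj) in state M, re-deriving which predecessor attains
  // the stored triple; preference order M > Ix > Iy > fresh start.
  int i = bi, j = bj, state = 0;  // 0=M 1=Ix 2=Iy
  int ident = 0, mm = 0, gaps = 0;
  int ai_end = bi, bj_end = bj, ai_start = bi, bj_start = bj;
  while (true) {
    if (state == 0) {
      bool ok = iupac_ok(av[i - 1], bv[j - 1]);
      if (ok) ++ident; else ++mm;
      ai_start = i; bj_start = j;
      Tri cur = M[idx(i, j)];
      Tri need = {cur.s - (ok ? match : mismatch), cur.g, cur.m - (ok ? 0 : 1), cur.o};
      --i; --j;
      if (same(need, ZERO)) break;
      if (same(M[idx(i, j)], need)) state = 0;
      else if (same(Ix[idx(i, j)], need)) state = 1;
      else if (same(Iy[idx(i, j)], need)) state = 2;
      else stop("traceback failure (M)");
    } else if (state == 1) {
      ++gaps;
      Tri cur = Ix[idx(i, j)];
      Tri open = {cur.s - gap_open - gap_ext, cur.g - 1, cur.m, cur.o - 1};
      Tri ext  = {cur.s - gap_ext, cur.g - 1, cur.m, cur.o};
      --i;
      if (M[idx(i, j)].s > NEG && same(M[idx(i, j)], open)) state = 0;
      else if (Ix[idx(i, j)].s > NEG && same(Ix[idx(i, j)], ext)) state = 1;
      else if (Iy[idx(i, j)].s > NEG && same(Iy[idx(i, j)], open)) state = 2;
      else stop("traceback failure (Ix)");
    } else {
      ++gaps;
      Tri cur = Iy[idx(i, j)];
      Tri open = {cur.s - gap_open - gap_ext, cur.g - 1, cur.m, cur.o - 1};
      Tri ext  = {cur.s - gap_ext, cur.g - 1, cur.m, cur.o};
      --j;
      if (M[idx(i, j)].s > NEG && same(M[idx(i, j)], open)) state = 0;
      else if (Iy[idx(i, j)].s > NEG && same(Iy[idx(i, j)], ext)) state = 2;
      else if (Ix[idx(i, j)].s > NEG && same(Ix[idx(i, j)], open)) state = 1;
      else stop("traceback failure (Iy)");
    }
  }

  return List::create(
    _["score"] = best.s, _["identities"] = ident, _["mismatches"] = mm,
    _["gaps"] = gaps, _["a_start"] = ai_start, _["a_end"] = ai_end,
    _["b_start"] = bj_start, _["b_end"] = bj_end,
    _["columns"] = ident + mm + gaps);
}

// IUPAC-aware reverse complement (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H,
// S/W/N self-complementary).
// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  static const std::string from = "ACGTURYSWKMBDHVN";
  static const std::string to   = "TGCAAYRSWMKVHDBN";
  int comp[256];
  for (int i = 0; i < 256; ++i) comp[i] = -1;
  for (size_t i = 0; i < from.size(); ++i) {
    comp[(unsigned char)from[i]] = to[i];
    comp[(unsigned char)std::tolower(from[i])] = to[i];
  }
  CharacterVector out(seqs.size());
  for (R_xlen_t k = 0; k < seqs.size(); ++k) {
    std::string s = as<std::string>(seqs[k]);
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) {
      int c = comp[(unsigned char)s[s.size() - 1 - i]];
      if (c < 0)
        stop("non-IUPAC character '%c' in sequence", s[s.size() - 1 - i]);
      r[i] = (char)c;
    }
    out[k] = r;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
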