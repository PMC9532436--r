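// V(D)J junction decomposition.
//
// Splits a junction nucleotide sequence into a V-templated prefix, up to two
// D-templated interior matches, a J-templated suffix, palindromic (P)
// nucleotides at untrimmed germline ends, and non-templated (N) additions.
// Objective is lexicographic: (1) minimise N, i.e. maximise templated + P;
// (2) maximise templated; (3) larger V match; (4) larger J match; (5)
// leftmost then longest first (then second) D match, lowest segment index.
// Exact matching only (no mismatches). P nucleotides are recognised only
// adjacent to an untrimmed germline end, as the reverse complement of that
// end, up to max_p nucleotides.

#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
  }
  return 'N';
}

struct Iv {          // a D match interval on the junction
  int s, e;          // junction coords [s, e)
  int d;             // segment index
  int dpos;          // offset of match within the D segment
};

struct Cand {
  int T = -1, P = -1, v = 0, j = 0;
  int nIv = 0;
  Iv iv[2];
  int pv = 0, pj = 0, p5d = 0, p3d = 0;
  bool valid = false;
};

// lexicographic preference
static bool better(const Cand &a, const Cand &b) {
  if (!b.valid) return true;
  if (a.T + a.P != b.T + b.P) return a.T + a.P > b.T + b.P;
  if (a.T != b.T) return a.T > b.T;
  if (a.v != b.v) return a.v > b.v;
  if (a.j != b.j) return a.j > b.j;
  int a1s = a.nIv > 0 ? a.iv[0].s : INT_MAX;
  int b1s = b.nIv > 0 ? b.iv[0].s : INT_MAX;
  if (a1s != b1s) return a1s < b1s;
  int a1l = a.nIv > 0 ? a.iv[0].e - a.iv[0].s : 0;
  int b1l = b.nIv > 0 ? b.iv[0].e - b.iv[0].s : 0;
  if (a1l != b1l) return a1l > b1l;
  int a2s = a.nIv > 1 ? a.iv[1].s : INT_MAX;
  int b2s = b.nIv > 1 ? b.iv[1].s : INT_MAX;
  if (a2s != b2s) return a2s < b2s;
  int a2l = a.nIv > 1 ? a.iv[1].e - a.iv[1].s : 0;
  int b2l = b.nIv > 1 ? b.iv[1].e - b.iv[1].s : 0;
  if (a2l != b2l) return a2l > b2l;
  int a1d = a.nIv > 0 ? a.iv[0].d : INT_MAX;
  int b1d = b.nIv > 0 ? b.iv[0].d : INT_MAX;
  if (a1d != b1d) return a1d < b1d;
  int a2d = a.nIv > 1 ? a.iv[1].d : INT_MAX;
  int b2d = b.nIv > 1 ? b.iv[1].d : INT_MAX;
  return a2d < b2d;
}

// maximal palindromic run length after an untrimmed V end
static int pal_after_v(const std::string &jx, const std::string &vt,
                       int v, int max_p) {
  int k = 0, L = jx.size(), vl = vt.size();
  while (k < max_p && v + k < L && k < vl &&
         jx[v + k] == comp(vt[vl - 1 - k])) ++k;
  return k;
}

// maximal palindromic run length before an untrimmed J start at position pos
static int pal_before_j(const std::string &jx, const std::string &jt,
                        int pos, int max_p) {
  int k = 0, jl = jt.size();
  while (k < max_p && pos - 1 - k >= 0 && k < jl &&
         jx[pos - 1 - k] == comp(jt[k])) ++k;
  return k;
}

// P claims on the gaps around the chosen intervals; fills pv/pj/p5d/p3d
static void assign_p(Cand &c, const std::string &jx, const std::string &vt,
                     const std::string &jt,
                     const std::vector<std::string> &ds,
                     int L, int max_p) {
  c.pv = c.pj = c.p5d = c.p3d = 0;
  int nseg = c.nIv;
  // gap boundaries: gap g runs [lo[g], hi[g])
  int lo[3], hi[3];
  int ng = nseg + 1;
  lo[0] = c.v;
  for (int i = 0; i < nseg; ++i) { hi[i] = c.iv[i].s; lo[i + 1] = c.iv[i].e; }
  hi[ng - 1] = L - c.j;
  // left/right claims per gap
  int lmax[3] = {0, 0, 0}, rmax[3] = {0, 0, 0};
  int *lslot[3] = {nullptr, nullptr, nullptr};
  int *rslot[3] = {nullptr, nullptr, nullptr};
  if (c.v == (int)vt.size() && c.v > 0) {
    lmax[0] = pal_after_v(jx, vt, c.v, max_p);
    lslot[0] = &c.pv;
  }
  if (c.j == (int)jt.size() && c.j > 0) {
    rmax[ng - 1] = pal_before_j(jx, jt, L - c.j, max_p);
    rslot[ng - 1] = &c.pj;
  }
  // P is recognised at the V 3' and J 5' ends only: D-end palindromes are
  // left as N so that templated coverage is never traded away for P
  (void)ds;
  int ptot = 0;
  for (int g = 0; g < ng; ++g) {
    int space = hi[g] - lo[g];
    if (space <= 0) continue;
    int lk = std::min(lmax[g], space);
    int rk = std::min(rmax[g], space - lk);
    if (lslot[g] && lk > 0) *lslot[g] += lk;
    if (rslot[g] && rk > 0) *rslot[g] += rk;
    ptot += lk + rk;
  }
  c.P = ptot;
}

// [[Rcpp::export(name = ".decompose_cpp")]]
List decompose_cpp(std::string junction, std::string v_template,
                   std::string j_template, CharacterVector d_seqs,
                   int min_d_match, int max_p, int max_d) {
  const std::string jx = junction;
  const int L = jx.size();
  std::vector<std::string> ds;
  for (int i = 0; i < d_seqs.size(); ++i) ds.push_back(as<std::string>(d_seqs[i]));

  int maxv = 0;
  while (maxv < L && maxv < (int)v_template.size() &&
         jx[maxv] == v_template[maxv]) ++maxv;
  int maxj = 0;
  while (maxj < L && maxj < (int)j_template.size() &&
         jx[L - 1 - maxj] == j_template[j_template.size() - 1 - maxj]) ++maxj;

  // maximal exact match runs between junction and each D segment
  std::vector<Iv> runs;
  for (size_t di = 0; di < ds.size(); ++di) {
    const std::string &d = ds[di];
    int dl = d.size();
    for (int s0 = -(dl - 1); s0 < L; ++s0) {   // diagonal offset
      int i = std::max(0, s0), k = i - s0;
      if (k >= dl) continue;
      if (i > 0 && k > 0 && jx[i - 1] == d[k - 1]) continue;  // not run start
      while (i < L && k < dl) {
        if (jx[i] == d[k]) {
          int rs = i, rk = k;
          while (i < L && k < dl && jx[i] == d[k]) { ++i; ++k; }
          if (i - rs >= min_d_match) {
            Iv iv; iv.s = rs; iv.e = i; iv.d = (int)di; iv.dpos = rk;
            runs.push_back(iv);
          }
        } else { ++i; ++k; }
      }
    }
  }

  Cand best;
  std::vector<Iv> win;
  for (int v = maxv; v >= 0; --v) {
    for (int j = maxj; j >= 0; --j) {
      if (v + j > L) continue;
      int a = v, b = L - j;
      // clip runs to window
      win.clear();
      for (const Iv &r : runs) {
        int s = std::max(r.s, a), e = std::min(r.e, b);
        if (e - s >= min_d_match) {
          Iv c2; c2.s = s; c2.e = e; c2.d = r.d; c2.dpos = r.dpos + (s - r.s);
          win.push_back(c2);
        }
      }
      // no-D candidate
      {
        Cand c; c.v = v; c.j = j; c.nIv = 0; c.T = v + j; c.valid = true;
        assign_p(c, jx, v_template, j_template, ds, L, max_p);
        if (better(c, best)) best = c;
      }
      if (max_d >= 1) {
        for (size_t x = 0; x < win.size(); ++x) {
          Cand c; c.v = v; c.j = j; c.nIv = 1; c.iv[0] = win[x];
          c.T = v + j + (win[x].e - win[x].s); c.valid = true;
          assign_p(c, jx, v_template, j_template, ds, L, max_p);
          if (better(c, best)) best = c;
        }
      }
      if (max_d >= 2) {
        for (size_t x = 0; x < win.size(); ++x) {
          for (size_t y = 0; y < win.size(); ++y) {
            if (x == y) continue;
            Iv A = win[x], B = win[y];
            if (A.s > B.s || (A.s == B.s && A.e >= B.e)) continue;
            Iv A2 = A, B2 = B;
            if (A.e > B.s) {
              // overlapping runs: realise the union with a split point x;
              // the largest valid first piece dominates under the tie-break
              int x = std::min(A.e, B.e - min_d_match);
              int xlo = std::max(B.s, A.s + min_d_match);
              if (x < xlo) continue;
              A2.e = x;
              B2.dpos += x - B2.s; B2.s = x;
            }
            if (A2.e - A2.s < min_d_match || B2.e - B2.s < min_d_match)
              continue;
            Cand c; c.v = v; c.j = j; c.nIv = 2;
            c.iv[0] = A2; c.iv[1] = B2;
            c.T = v + j + (A2.e - A2.s) + (B2.e - B2.s); c.valid = true;
            assign_p(c, jx, v_template, j_template, ds, L, max_p);
            if (better(c, best)) best = c;
          }
        }
      }
    }
  }

  // reconstruct N regions from unassigned positions
  std::vector<bool> used(L, false);
  for (int i = 0; i < best.v; ++i) used[i] = true;
  for (int i = L - best.j; i < L; ++i) used[i] = true;
  for (int s = 0; s < best.nIv; ++s)
    for (int i = best.iv[s].s; i < best.iv[s].e; ++i) used[i] = true;
  // P positions: recompute the same greedy allocation to mark them
  {
    Cand tmp = best;
    // mark P by re-deriving gap allocations
    int nseg = best.nIv;
    int lo[3], hi[3]; int ng = nseg + 1;
    lo[0] = best.v;
    for (int i = 0; i < nseg; ++i) { hi[i] = best.iv[i].s; lo[i + 1] = best.iv[i].e; }
    hi[ng - 1] = L - best.j;
    int lmax[3] = {0,0,0}, rmax[3] = {0,0,0};
    if (best.v == (int)v_template.size() && best.v > 0)
      lmax[0] = pal_after_v(jx, v_template, best.v, max_p);
    if (best.j == (int)j_template.size() && best.j > 0)
      rmax[ng - 1] = pal_before_j(jx, j_template, L - best.j, max_p);
    for (int g = 0; g < ng; ++g) {
      int space = hi[g] - lo[g];
      if (space <= 0) continue;
      int lk = std::min(lmax[g], space);
      int rk = std::min(rmax[g], space - lk);
      for (int i = 0; i < lk; ++i) used[lo[g] + i] = true;
      for (int i = 0; i < rk; ++i) used[hi[g] - 1 - i] = true;
    }
    (void)tmp;
  }
  std::vector<std::string> nregions;
  int ntot = 0;
  for (int i = 0; i < L; ) {
    if (!used[i]) {
      int s = i;
      while (i < L && !used[i]) ++i;
      nregions.push_back(jx.substr(s, i - s));
      ntot += i - s;
    } else ++i;
  }

  CharacterVector dn(best.nIv);
  IntegerVector dstart(best.nIv), dlen(best.nIv), dposv(best.nIv);
  for (int i = 0; i < best.nIv; ++i) {
    dn[i] = d_seqs.size() > 0 ? as<std::string>(d_seqs[best.iv[i].d]) : "";
    dstart[i] = best.iv[i].s;
    dlen[i] = best.iv[i].e - best.iv[i].s;
    dposv[i] = best.iv[i].dpos;
  }
  IntegerVector didx(best.nIv);
  for (int i = 0; i < best.nIv; ++i) didx[i] = best.iv[i].d + 1;

  return List::create(
    _["v_match_len"] = best.v,
    _["j_match_len"] = best.j,
    _["d_index"] = didx,
    _["d_start"] = dstart,
    _["d_length"] = dlen,
    _["d_offset"] = dposv,
    _["p_nt_5v"] = best.pv,
    _["p_nt_3j"] = best.pj,
    _["p_nt_5d"] = best.p5d,
    _["p_nt_3d"] = best.p3d,
    _["n_regions"] = wrap(nregions),
    _["n_additions_total"] = ntot,
    _["templated_total"] = best.T,
    _["junction_nt_length"] = L);
}
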