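#include "nn.h"
#include <algorithm>
using namespace Rcpp;

// Intermolecular duplex dynamic program (RNAhybrid-style): antiparallel
// monotone pairing between an sRNA window s (5'->3') and an mRNA m, with
// stacks, bulges and interior loops only (per-side gap <= max_loop), no
// intramolecular pairs, no branching. Terminal AU/GU charged at both duplex
// ends and at both pairs flanking every non-stack loop, matching the
// intramolecular model.

namespace {

struct Cand {
  double e;
  int i, j;                       // last pair (sRNA i, mRNA j), 1-based
  std::vector<int> si, mj;        // full pairing, sRNA ascending
  int m_lo, m_hi, s_lo, s_hi;
};

}  // namespace

// [[Rcpp::export]]
List hybrid_cpp(IntegerVector s_codes, IntegerVector m_codes, List par,
                int max_loop, int n_subopt, double overlap_frac,
                int seed_lo, int seed_hi, int min_seed_overlap) {
  NNParams p = params_from_list(par);
  int ns = s_codes.size(), nm = m_codes.size();
  std::vector<double> D((size_t)(ns + 1) * (nm + 1), 1e18);
  std::vector<int> bpi((size_t)(ns + 1) * (nm + 1), 0),
                   bpj((size_t)(ns + 1) * (nm + 1), 0);
  // sRNA index ascending pairs with mRNA index descending (antiparallel)
  for (int i = 1; i <= ns; ++i) {
    for (int j = nm; j >= 1; --j) {
      int t = pair_type(s_codes[i - 1], m_codes[j - 1]);
      if (t < 0) continue;
      double best = p.duplex_init + p.au(t);  // duplex opens at (i,j)
      int bi = 0, bj = 0;
      for (int pi = std::max(1, i - 1 - max_loop); pi <= i - 1; ++pi) {
        int g1 = i - pi - 1;
        for (int qj = j + 1; qj <= std::min(nm, j + 1 + max_loop); ++qj) {
          int g2 = qj - j - 1;
          double dprev = D[(size_t)pi * (nm + 1) + qj];
          if (dprev >= 1e17) continue;
          int tp = pair_type(s_codes[pi - 1], m_codes[qj - 1]);
          double e = dprev + p.interior_loop(tp, t, g1, g2);
          if (e < best) { best = e; bi = pi; bj = qj; }
        }
      }
      D[(size_t)i * (nm + 1) + j] = best;
      bpi[(size_t)i * (nm + 1) + j] = bi;
      bpj[(size_t)i * (nm + 1) + j] = bj;
    }
  }
  // candidate duplexes: close at (i,j), charge terminal AU at the last pair
  std::vector<Cand> cands;
  for (int i = 1; i <= ns; ++i) {
    for (int j = 1; j <= nm; ++j) {
      double d = D[(size_t)i * (nm + 1) + j];
      if (d >= 1e17) continue;
      int t = pair_type(s_codes[i - 1], m_codes[j - 1]);
      double e = d + p.au(t);
      if (e >= 0.0) continue;  // only energetically favorable duplexes
      Cand c;
      c.e = e; c.i = i; c.j = j;
      int ci = i, cj = j;
      while (ci > 0) {
        c.si.push_back(ci);
        c.mj.push_back(cj);
        int ni = bpi[(size_t)ci * (nm + 1) + cj];
        int nj = bpj[(size_t)ci * (nm + 1) + cj];
        ci = ni; cj = nj;
      }
      std::reverse(c.si.begin(), c.si.end());
      std::reverse(c.mj.begin(), c.mj.end());
      c.s_lo = c.si.front(); c.s_hi = c.si.back();
      c.m_lo = c.mj.back();  c.m_hi = c.mj.front();
      if (min_seed_overlap > 0) {
        int hits = 0;
        for (size_t k = 0; k < c.si.size(); ++k)
          if (c.si[k] >= seed_lo && c.si[k] <= seed_hi) ++hits;
        if (hits < min_seed_overlap) continue;
      }
      cands.push_back(c);
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.e != b.e) return a.e < b.e;
    if (a.m_lo != b.m_lo) return a.m_lo < b.m_lo;
    if (a.s_lo != b.s_lo) return a.s_lo < b.s_lo;
    return a.si.size() < b.si.size();
  });
  // greedy non-redundant selection on mRNA intervals
  std::vector<const Cand*> kept;
  for (size_t c = 0; c < cands.size() && (int)kept.size() < n_subopt + 1; ++c) {
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      int lo = std::max(cands[c].m_lo, kept[k]->m_lo);
      int hi = std::min(cands[c].m_hi, kept[k]->m_hi);
      int ov = std::max(0, hi - lo + 1);
      int len = std::min(cands[c].m_hi - cands[c].m_lo + 1,
                         kept[k]->m_hi - kept[k]->m_lo + 1);
      if ((double)ov / (double)len >= overlap_frac) { ok = false; break; }
    }
    if (ok) kept.push_back(&cands[c]);
  }
  List out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) {
    int np = kept[k]->si.size();
    IntegerMatrix pm(np, 2);
    for (int q = 0; q < np; ++q) {
      pm(q, 0) = kept[k]->si[q];
      pm(q, 1) = kept[k]->mj[q];
    }
    out[k] = List::create(_["pairs"] = pm, _["dG_hybrid"] = kept[k]->e);
  }
  return out;
}
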