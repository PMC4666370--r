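#include "nn.h"
using namespace Rcpp;

// McCaskill-style inside/outside recursions and stochastic traceback, built on
// the same loop-based energy model as eval_structure_cpp:
//   Zb(i,j): substructure closed by pair (i,j)
//   Zm1(i,j): one multiloop branch starting exactly at i, trailing unpaired to j
//   Zm(i,j): >= 1 multiloop branches on [i,j]
//   ze(j): exterior partition function on prefix [1,j]
// Multiloop energy: ml_close + au(closing) + sum(ml_branch + au(branch)) +
// ml_unpaired per unpaired nucleotide.

namespace {

struct Arrays {
  int n;
  std::vector<double> zb, zm, zm1;
  std::vector<double> ze;
  std::vector<int> codes;
  NNParams p;
  double& ZB(int i, int j)  { return zb[(size_t)i * (n + 2) + j]; }
  double& ZM(int i, int j)  { return zm[(size_t)i * (n + 2) + j]; }
  double& ZM1(int i, int j) { return zm1[(size_t)i * (n + 2) + j]; }
  int type(int i, int j) const { return pair_type(codes[i - 1], codes[j - 1]); }
  bool pairable(int i, int j) const { return j - i > MIN_HP && type(i, j) >= 0; }
  double eau(int t) const { return std::exp(-p.au(t) / p.RT); }
};

void fill_inside(Arrays& A) {
  int n = A.n;
  const NNParams& p = A.p;
  double RT = p.RT;
  A.zb.assign((size_t)(n + 2) * (n + 2), 0.0);
  A.zm.assign((size_t)(n + 2) * (n + 2), 0.0);
  A.zm1.assign((size_t)(n + 2) * (n + 2), 0.0);
  for (int d = MIN_HP + 1; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (A.pairable(i, j)) {
        int t = A.type(i, j);
        double z = std::exp(-(p.hairpin_e(j - i - 1) + p.au(t)) / RT);
        // single enclosed pair: stack / bulge / interior loop
        for (int k = i + 1; k <= std::min(i + 1 + p.max_loop, j - MIN_HP - 2); ++k) {
          int g1 = k - i - 1;
          for (int l = j - 1; l >= k + MIN_HP + 1; --l) {
            int g2 = j - l - 1;
            if (g1 + g2 > p.max_loop) break;
            if (!A.pairable(k, l)) continue;
            int tin = A.type(k, l);
            z += std::exp(-p.interior_loop(t, tin, g1, g2) / RT) * A.ZB(k, l);
          }
        }
        // multiloop: closing pair (i,j), split at start k of last branch
        double zml = 0.0;
        for (int k = i + 2; k <= j - 2; ++k)
          zml += A.ZM(i + 1, k - 1) * A.ZM1(k, j - 1);
        z += zml * std::exp(-(p.ml_close + p.au(t)) / RT);
        A.ZB(i, j) = z;
      }
      // Zm1(i,j): branch pair (i,l), l <= j, trailing unpaired j-l
      double z1 = 0.0;
      for (int l = i + MIN_HP + 1; l <= j; ++l) {
        if (!A.pairable(i, l)) continue;
        int tb = A.type(i, l);
        z1 += A.ZB(i, l) *
              std::exp(-(p.ml_branch + p.au(tb) + p.ml_unpaired * (j - l)) / RT);
      }
      A.ZM1(i, j) = z1;
      // Zm(i,j): split by start k of last branch
      double zm = 0.0;
      for (int k = i; k <= j; ++k) {
        if (A.ZM1(k, j) == 0.0) continue;
        double left = std::exp(-p.ml_unpaired * (k - i) / RT);
        if (k > i) left += A.ZM(i, k - 1);
        zm += left * A.ZM1(k, j);
      }
      A.ZM(i, j) = zm;
    }
  }
  A.ze.assign(n + 1, 1.0);
  for (int j = 1; j <= n; ++j) {
    double z = A.ze[j - 1];
    for (int i = 1; i <= j - MIN_HP - 1; ++i)
      if (A.pairable(i, j))
        z += A.ze[i - 1] * A.ZB(i, j) * A.eau(A.type(i, j));
    A.ze[j] = z;
  }
}

Arrays make_arrays(IntegerVector seq_codes, List par) {
  Arrays A;
  A.p = params_from_list(par);
  A.n = seq_codes.size();
  A.codes.assign(seq_codes.begin(), seq_codes.end());
  fill_inside(A);
  return A;
}

// splitmix64: integer-state RNG so sampling is platform-reproducible
struct Rng {
  uint64_t x;
  explicit Rng(int seed) : x((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL
                             + 0x243F6A8885A308D3ULL) {}
  double next() {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct Task { int kind, i, j; };  // 0=EXT prefix [1,j], 1=ZB, 2=ZM, 3=ZM1

void sample_one(Arrays& A, Rng& rng, std::vector<std::pair<int,int> >& pairs) {
  const NNParams& p = A.p;
  double RT = p.RT;
  std::vector<Task> st;
  Task t0; t0.kind = 0; t0.i = 1; t0.j = A.n; st.push_back(t0);
  while (!st.empty()) {
    Task tk = st.back(); st.pop_back();
    if (tk.kind == 0) {
      int j = tk.j;
      while (j > 0) {
        double r = rng.next() * A.ze[j];
        if (r < A.ze[j - 1]) { --j; continue; }
        r -= A.ze[j - 1];
        int isel = -1;
        double cum = 0.0;
        for (int i = 1; i <= j - MIN_HP - 1; ++i) {
          if (!A.pairable(i, j)) continue;
          cum += A.ze[i - 1] * A.ZB(i, j) * A.eau(A.type(i, j));
          if (r < cum) { isel = i; break; }
          isel = i;  // numeric fallback: keep last valid
        }
        if (isel < 0) { --j; continue; }
        pairs.push_back(std::make_pair(isel, j));
        Task t; t.kind = 1; t.i = isel; t.j = j; st.push_back(t);
        j = isel - 1;
      }
    } else if (tk.kind == 1) {
      int i = tk.i, j = tk.j;
      int t = A.type(i, j);
      double r = rng.next() * A.ZB(i, j);
      double cum = std::exp(-(p.hairpin_e(j - i - 1) + p.au(t)) / RT);
      if (r < cum) continue;
      bool done = false;
      for (int k = i + 1; k <= std::min(i + 1 + p.max_loop, j - MIN_HP - 2) && !done; ++k) {
        int g1 = k - i - 1;
        for (int l = j - 1; l >= k + MIN_HP + 1; --l) {
          int g2 = j - l - 1;
          if (g1 + g2 > p.max_loop) break;
          if (!A.pairable(k, l)) continue;
          int tin = A.type(k, l);
          cum += std::exp(-p.interior_loop(t, tin, g1, g2) / RT) * A.ZB(k, l);
          if (r < cum) {
            pairs.push_back(std::make_pair(k, l));
            Task tt; tt.kind = 1; tt.i = k; tt.j = l; st.push_back(tt);
            done = true; break;
          }
        }
      }
      if (done) continue;
      double mlf = std::exp(-(p.ml_close + p.au(t)) / RT);
      int ksel = -1;
      for (int k = i + 2; k <= j - 2; ++k) {
        double w = mlf * A.ZM(i + 1, k - 1) * A.ZM1(k, j - 1);
        if (w <= 0.0) continue;
        cum += w;
        ksel = k;
        if (r < cum) break;
      }
      if (ksel < 0) continue;  // numeric edge: treat as hairpin
      Task tm; tm.kind = 2; tm.i = i + 1; tm.j = ksel - 1; st.push_back(tm);
      Task tb; tb.kind = 3; tb.i = ksel; tb.j = j - 1; st.push_back(tb);
    } else if (tk.kind == 2) {
      int i = tk.i, j = tk.j;
      double r = rng.next() * A.ZM(i, j);
      double cum = 0.0;
      for (int k = i; k <= j; ++k) {
        if (A.ZM1(k, j) == 0.0) continue;
        double w1 = std::exp(-p.ml_unpaired * (k - i) / RT) * A.ZM1(k, j);
        cum += w1;
        if (r < cum) {
          Task t1; t1.kind = 3; t1.i = k; t1.j = j; st.push_back(t1);
          break;
        }
        if (k > i && A.ZM(i, k - 1) > 0.0) {
          double w2 = A.ZM(i, k - 1) * A.ZM1(k, j);
          cum += w2;
          if (r < cum) {
            Task t1; t1.kind = 2; t1.i = i; t1.j = k - 1; st.push_back(t1);
            Task t2; t2.kind = 3; t2.i = k; t2.j = j; st.push_back(t2);
            break;
          }
        }
      }
    } else {
      int i = tk.i, j = tk.j;
      double r = rng.next() * A.ZM1(i, j);
      double cum = 0.0;
      for (int l = i + MIN_HP + 1; l <= j; ++l) {
        if (!A.pairable(i, l)) continue;
        int tb = A.type(i, l);
        cum += A.ZB(i, l) *
               std::exp(-(p.ml_branch + p.au(tb) + p.ml_unpaired * (j - l)) / RT);
        if (r < cum) {
          pairs.push_back(std::make_pair(i, l));
          Task tt; tt.kind = 1; tt.i = i; tt.j = l; st.push_back(tt);
          break;
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List partition_cpp(IntegerVector seq_codes, List par) {
  Arrays A = make_arrays(seq_codes, par);
  double Z = A.ze[A.n];
  return List::create(_["Z"] = Z,
                      _["ensemble_free_energy"] = -A.p.RT * std::log(Z));
}

// [[Rcpp::export]]
List sample_cpp(IntegerVector seq_codes, List par, int n, int seed) {
  Arrays A = make_arrays(seq_codes, par);
  Rng rng(seed);
  List out(n);
  for (int s = 0; s < n; ++s) {
    std::vector<std::pair<int,int> > pairs;
    sample_one(A, rng, pairs);
    IntegerMatrix m(pairs.size(), 2);
    for (size_t k = 0; k < pairs.size(); ++k) {
      m(k, 0) = pairs[k].first;
      m(k, 1) = pairs[k].second;
    }
    out[s] = m;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix pairprob_cpp(IntegerVector seq_codes, List par) {
  Arrays A = make_arrays(seq_codes, par);
  int n = A.n;
  const NNParams& p = A.p;
  double RT = p.RT;
  double Z = A.ze[n];
  // interval exterior partition function ZE(i,j), empty interval = 1
  std::vector<double> ZE((size_t)(n + 2) * (n + 2), 1.0);
  for (int i = 1; i <= n; ++i) {
    for (int j = i; j <= n; ++j) {
      double z = ZE[(size_t)i * (n + 2) + (j - 1)];
      for (int k = i; k <= j - MIN_HP - 1; ++k)
        if (A.pairable(k, j))
          z += ZE[(size_t)i * (n + 2) + (k - 1)] * A.ZB(k, j) * A.eau(A.type(k, j));
      ZE[(size_t)i * (n + 2) + j] = z;
    }
  }
  std::vector<double> pout((size_t)(n + 2) * (n + 2), 0.0);
  NumericMatrix P(n, n);
  for (int d = n - 1; d >= MIN_HP + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (!A.pairable(i, j)) continue;
      int t = A.type(i, j);
      double val = ZE[(size_t)1 * (n + 2) + (i - 1)] *
                   (j + 1 <= n ? ZE[(size_t)(j + 1) * (n + 2) + n] : 1.0) *
                   A.eau(t);
      // enclosed directly by (k,l) through stack/bulge/interior loop
      for (int k = i - 1; k >= std::max(1, i - 1 - p.max_loop); --k) {
        int g1 = i - k - 1;
        for (int l = j + 1; l <= n; ++l) {
          int g2 = l - j - 1;
          if (g1 + g2 > p.max_loop) break;
          if (!A.pairable(k, l)) continue;
          int tout = A.type(k, l);
          val += pout[(size_t)k * (n + 2) + l] *
                 std::exp(-p.interior_loop(tout, t, g1, g2) / RT);
        }
      }
      // (i,j) a branch of a multiloop closed by (k,l)
      for (int k = 1; k <= i - 1; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (!A.pairable(k, l)) continue;
          double po = pout[(size_t)k * (n + 2) + l];
          if (po == 0.0) continue;
          int tout = A.type(k, l);
          double ul = std::exp(-p.ml_unpaired * (i - k - 1) / RT);
          double ur = std::exp(-p.ml_unpaired * (l - j - 1) / RT);
          double zml = (k + 1 <= i - 1) ? A.ZM(k + 1, i - 1) : 0.0;
          double zmr = (j + 1 <= l - 1) ? A.ZM(j + 1, l - 1) : 0.0;
          double M = (zml + ul) * (zmr + ur) - ul * ur;
          if (M <= 0.0) continue;
          val += po * M *
                 std::exp(-(p.ml_close + p.au(tout) + p.ml_branch + p.au(t)) / RT);
        }
      }
      pout[(size_t)i * (n + 2) + j] = val;
      double prob = A.ZB(i, j) * val / Z;
      P(i - 1, j - 1) = prob;
      P(j - 1, i - 1) = prob;
    }
  }
  return P;
}
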