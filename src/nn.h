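#ifndef SRNATARGET_NN_H
#define SRNATARGET_NN_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Base codes: A=0, C=1, G=2, U=3.
// Pair types: 0=AU, 1=UA, 2=GC, 3=CG, 4=GU, 5=UG, -1=disallowed.
inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct NNParams {
  double RT;
  double stack[6][6];
  std::vector<double> hairpin;   // index = loop length (1-based); [0] unused
  std::vector<double> bulge;
  std::vector<double> internal;
  double lxc;                    // logarithmic loop extrapolation coefficient
  double ml_close, ml_branch, ml_unpaired;
  double terminal_au;
  double duplex_init;
  int max_loop;

  double au(int t) const { return (t == 2 || t == 3) ? 0.0 : terminal_au; }

  static double tab(const std::vector<double>& v, int len, double lxc) {
    int m = (int)v.size() - 1;
    if (len <= 0) return 1e9;
    if (len <= m) return v[len];
    return v[m] + lxc * std::log((double)len / (double)m);
  }
  double hairpin_e(int len) const { return tab(hairpin, len, lxc); }
  double bulge_e(int len)   const { return tab(bulge, len, lxc); }
  double internal_e(int len) const { return tab(internal, len, lxc); }

  // Energy of the loop between an outer pair (type t_out) and the directly
  // enclosed pair (type t_in), with g1/g2 unpaired on the two sides.
  // Stacks carry no terminal AU; every other loop charges it on both pairs.
  double interior_loop(int t_out, int t_in, int g1, int g2) const {
    if (g1 == 0 && g2 == 0) return stack[t_out][t_in];
    double e = (g1 == 0 || g2 == 0) ? bulge_e(g1 + g2) : internal_e(g1 + g2);
    return e + au(t_out) + au(t_in);
  }
};

NNParams params_from_list(Rcpp::List par);

// Minimum unpaired nucleotides in a hairpin loop.
const int MIN_HP = 3;

#endif
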