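#include "nn.h"
using namespace Rcpp;

NNParams params_from_list(List par) {
  NNParams p;
  p.RT = as<double>(par["rt"]);
  NumericMatrix st = par["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) p.stack[i][j] = st(i, j);
  NumericVector hp = par["hairpin"], bu = par["bulge"], il = par["internal"];
  p.hairpin.assign(hp.size() + 1, 1e9);
  for (int i = 0; i < hp.size(); ++i) p.hairpin[i + 1] = hp[i];
  p.bulge.assign(bu.size() + 1, 1e9);
  for (int i = 0; i < bu.size(); ++i) p.bulge[i + 1] = bu[i];
  p.internal.assign(il.size() + 1, 1e9);
  for (int i = 0; i < il.size(); ++i) p.internal[i + 1] = il[i];
  p.lxc = as<double>(par["lxc"]);
  p.ml_close = as<double>(par["ml_close"]);
  p.ml_branch = as<double>(par["ml_branch"]);
  p.ml_unpaired = as<double>(par["ml_unpaired"]);
  p.terminal_au = as<double>(par["terminal_au"]);
  p.duplex_init = as<double>(par["duplex_init"]);
  p.max_loop = as<int>(par["max_loop"]);
  return p;
}

// Recursive loop-decomposition evaluation of the substructure closed by (i,j).
// mate[] is 1-based (0 = unpaired).
static double eval_closed(int i, int j, const std::vector<int>& mate,
                          const IntegerVector& s, const NNParams& p) {
  int t = pair_type(s[i - 1], s[j - 1]);
  if (t < 0) stop("disallowed pair in structure");
  std::vector<std::pair<int,int> > branches;
  int unpaired = 0;
  for (int k = i + 1; k < j; ++k) {
    if (mate[k] > k) { branches.push_back(std::make_pair(k, mate[k])); k = mate[k]; }
    else unpaired++;
  }
  double e = 0.0;
  if (branches.empty()) {
    e = p.hairpin_e(j - i - 1) + p.au(t);
  } else if (branches.size() == 1) {
    int k = branches[0].first, l = branches[0].second;
    int tin = pair_type(s[k - 1], s[l - 1]);
    if (tin < 0) stop("disallowed pair in structure");
    e = p.interior_loop(t, tin, k - i - 1, j - l - 1);
  } else {
    e = p.ml_close + p.au(t) + p.ml_unpaired * unpaired;
    for (size_t b = 0; b < branches.size(); ++b) {
      int tb = pair_type(s[branches[b].first - 1], s[branches[b].second - 1]);
      if (tb < 0) stop("disallowed pair in structure");
      e += p.ml_branch + p.au(tb);
    }
  }
  for (size_t b = 0; b < branches.size(); ++b)
    e += eval_closed(branches[b].first, branches[b].second, mate, s, p);
  return e;
}

// [[Rcpp::export]]
double eval_structure_cpp(IntegerVector seq_codes, IntegerVector mate1, List par) {
  NNParams p = params_from_list(par);
  int n = seq_codes.size();
  std::vector<int> mate(n + 1, 0);
  for (int i = 1; i <= n; ++i) mate[i] = mate1[i - 1];
  double e = 0.0;
  for (int k = 1; k <= n; ++k) {
    if (mate[k] > k) {
      int t = pair_type(seq_codes[k - 1], seq_codes[mate[k] - 1]);
      if (t < 0) stop("disallowed pair in structure");
      e += p.au(t);  // exterior-loop helix end
      e += eval_closed(k, mate[k], mate, seq_codes, p);
      k = mate[k];
    }
  }
  return e;
}
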