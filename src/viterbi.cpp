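// Local unihit Viterbi over match states: free entry/exit at any match
// state, plan7 core transitions inside, log2-odds emissions.  Mirrors
// the documented convention in R/viterbi.R; the exhaustive-path oracle
// used to validate it lives in R.
#include <Rcpp.h>
using namespace Rcpp;

// lm, li: M x 21 emission log-odds (column 0 = ambiguity code, 0 bits);
// x: residue codes 0..20; transition vectors are log2 probabilities
// out of node k (0-based).
// [[Rcpp::export(name = ".viterbi_dp")]]
List viterbi_dp(NumericMatrix lm, NumericMatrix li,
                NumericVector tmm, NumericVector tmi, NumericVector tmd,
                NumericVector tim, NumericVector tii,
                NumericVector tdm, NumericVector tdd,
                IntegerVector x, bool with_span) {
  const int M = lm.nrow(), L = x.size();
  std::vector<double> vm(M, R_NegInf), vi(M, R_NegInf), vd(M, R_NegInf);
  std::vector<double> nvm(M), nvi(M), nvd(M);
  std::vector<int> sm(M, NA_INTEGER), si(M, NA_INTEGER), sd(M, NA_INTEGER);
  std::vector<int> nsm(M), nsi(M), nsd(M);
  double best = R_NegInf;
  int best_start = NA_INTEGER, best_end = NA_INTEGER;

  for (int i = 0; i < L; ++i) {
    const int col = x[i];
    for (int k = 0; k < M; ++k) {
      // match: free entry, or from m/i/d of the previous node
      double bi = 0.0;  // entry
      int src = 0;
      if (k > 0) {
        const double c_m = vm[k - 1] + tmm[k - 1];
        const double c_i = vi[k - 1] + tim[k - 1];
        const double c_d = vd[k - 1] + tdm[k - 1];
        if (c_m > bi) { bi = c_m; src = 1; }
        if (c_i > bi) { bi = c_i; src = 2; }
        if (c_d > bi) { bi = c_d; src = 3; }
      }
      nvm[k] = lm(k, col) + bi;
      if (with_span) {
        nsm[k] = src == 0 ? i + 1
               : src == 1 ? sm[k - 1]
               : src == 2 ? si[k - 1] : sd[k - 1];
      }
      // insert: stay at node k
      const double a_m = vm[k] + tmi[k];
      const double a_i = vi[k] + tii[k];
      nvi[k] = li(k, col) + (a_m >= a_i ? a_m : a_i);
      if (with_span) nsi[k] = a_m >= a_i ? sm[k] : si[k];
    }
    // delete states consume no residue: propagate along current row
    nvd[0] = R_NegInf;
    if (with_span) nsd[0] = NA_INTEGER;
    for (int k = 1; k < M; ++k) {
      const double f_m = nvm[k - 1] + tmd[k - 1];
      const double f_d = nvd[k - 1] + tdd[k - 1];
      if (f_m >= f_d) {
        nvd[k] = f_m;
        if (with_span) nsd[k] = nsm[k - 1];
      } else {
        nvd[k] = f_d;
        if (with_span) nsd[k] = nsd[k - 1];
      }
    }
    for (int k = 0; k < M; ++k) {
      if (nvm[k] > best) {
        best = nvm[k];
        if (with_span) { best_start = nsm[k]; best_end = i + 1; }
      }
    }
    vm.swap(nvm); vi.swap(nvi); vd.swap(nvd);
    sm.swap(nsm); si.swap(nsi); sd.swap(nsd);
  }
  return List::create(_["bit_score"] = best,
                      _["span_start"] = best_start,
                      _["span_end"] = best_end);
}
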