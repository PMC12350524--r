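#include <Rcpp.h>
using namespace Rcpp;

// Bellman backup over a precomputed tabular model.
//
// Layouts (0-based, outcome index fastest so the inner loop is contiguous):
//   nxt[o + nO*(a + nA*s)]  next-state index (0-based)
//   rew[o + nO*(a + nA*s)]  immediate reward
// prob_mode: 0 = prob[o] shared across (s,a); 1 = prob[o + nO*s] (state-dependent,
// action-independent); 2 = prob[o + nO*(a + nA*s)] (full).
// rows: 0-based subset of states to update (supports batching / async blocks).
// [[Rcpp::export]]
NumericMatrix cpp_backup_tabular(IntegerVector rows, IntegerVector nxt,
                                 NumericVector rew, NumericVector prob,
                                 int prob_mode, int nS, int nA, int nO,
                                 NumericVector V, double gamma) {
  int nr = rows.size();
  NumericMatrix Q(nr, nA);
  for (int i = 0; i < nr; ++i) {
    int s = rows[i];
    for (int a = 0; a < nA; ++a) {
      R_xlen_t base = (R_xlen_t)nO * ((R_xlen_t)a + (R_xlen_t)nA * s);
      double acc = 0.0;
      for (int o = 0; o < nO; ++o) {
        R_xlen_t idx = base + o;
        double p;
        if (prob_mode == 0) p = prob[o];
        else if (prob_mode == 1) p = prob[(R_xlen_t)nO * s + o];
        else p = prob[idx];
        if (p > 0.0) acc += p * (rew[idx] + gamma * V[nxt[idx]]);
      }
      Q(i, a) = acc;
    }
  }
  return Q;
}

// Demand-weighted gather used by the platelet-bank (weekday-periodic) backup:
//   W[s, y] = sum_d pd[d] * V[idx[d + nD*(s + nstock*y)]]
// where V is the value vector of the *next* weekday's stock block and rows is a
// 0-based subset of stock states.
// [[Rcpp::export]]
NumericMatrix cpp_gather_expect(IntegerVector rows, IntegerVector idx,
                                NumericVector pd, int nD, int nstock, int nY,
                                NumericVector V) {
  int nr = rows.size();
  NumericMatrix W(nr, nY);
  for (int y = 0; y < nY; ++y) {
    R_xlen_t base_y = (R_xlen_t)nD * (R_xlen_t)nstock * y;
    for (int i = 0; i < nr; ++i) {
      R_xlen_t base = base_y + (R_xlen_t)nD * rows[i];
      double acc = 0.0;
      for (int d = 0; d < nD; ++d) acc += pd[d] * V[idx[base + d]];
      W(i, y) = acc;
    }
  }
  return W;
}
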