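#include <Rcpp.h>
using namespace Rcpp;

// Sequential proposal loop of the codon evolution model. Draws come from R's
// RNG (RNGScope), so results are reproducible under set.seed() in R.
// nt: nucleotide codes 1..4 (T,C,A,G order); codon index in the standard
// 64-codon table is 16(n1-1) + 4(n2-1) + n3.
//
// is_stop: length-64 logical; aa: length-64 integer amino-acid codes.
// Returns the evolved sequence plus a full proposal log.

// [[Rcpp::export(name = ".evolve_cds_cpp")]]
List evolve_cds_cpp(IntegerVector nt0, int n_prop, double omega,
                    LogicalVector is_stop, IntegerVector aa) {
  IntegerVector nt = clone(nt0);
  const int len = nt.size();
  IntegerVector site(n_prop), from(n_prop), to(n_prop);
  IntegerVector type(n_prop);  // 0 stop, 1 synonymous, 2 nonsynonymous
  LogicalVector acc(n_prop);
  const int step[3] = {16, 4, 1};

  for (int e = 0; e < n_prop; ++e) {
    int s = (int)(unif_rand() * len);
    if (s == len) s = len - 1;
    int pos = s % 3;
    int base = s - pos;
    int cur = nt[s];
    int pick = (int)(unif_rand() * 3.0);
    if (pick == 3) pick = 2;
    // the three alternatives to cur, in increasing order
    int alt = pick + 1 + (pick + 1 >= cur ? 1 : 0);
    int old_codon = 16 * (nt[base] - 1) + 4 * (nt[base + 1] - 1) + nt[base + 2];
    int new_codon = old_codon + step[pos] * (alt - cur);
    int ty;
    bool a;
    if (is_stop[new_codon - 1]) {
      ty = 0;
      a = false;
    } else if (aa[new_codon - 1] == aa[old_codon - 1]) {
      ty = 1;
      a = true;
    } else {
      ty = 2;
      a = unif_rand() < omega;
    }
    if (a) nt[s] = alt;
    site[e] = s + 1;
    from[e] = cur;
    to[e] = alt;
    type[e] = ty;
    acc[e] = a;
  }
  return List::create(
    _["nt"] = nt, _["site"] = site, _["from"] = from, _["to"] = to,
    _["type"] = type, _["accepted"] = acc
  );
}
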