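#include <Rcpp.h>
using namespace Rcpp;

// Two-state Viterbi decode in log space.
// States: 0 = homozygous background, 1 = residually heterozygous tract.
// Observations: 0 = hom call, 1 = het call.
// log_emit(state, obs); ties broken toward state 0 (homozygous).
// Log space is required: with switch probabilities of 1e-10 the joint path
// probability underflows doubles within a few thousand sites.
// [[Rcpp::export]]
IntegerVector viterbi2_cpp(IntegerVector obs, NumericVector log_prior,
                           NumericMatrix log_trans, NumericMatrix log_emit) {
  const int T = obs.size();
  IntegerVector path(T);
  if (T == 0) return path;
  std::vector<unsigned char> bp0(T), bp1(T);
  double p0 = log_prior[0] + log_emit(0, obs[0]);
  double p1 = log_prior[1] + log_emit(1, obs[0]);
  for (int t = 1; t < T; ++t) {
    const int o = obs[t];
    // into state 0
    double a = p0 + log_trans(0, 0);
    double b = p1 + log_trans(1, 0);
    double n0;
    if (a >= b) { n0 = a; bp0[t] = 0; } else { n0 = b; bp0[t] = 1; }
    // into state 1
    a = p0 + log_trans(0, 1);
    b = p1 + log_trans(1, 1);
    double n1;
    if (a >= b) { n1 = a; bp1[t] = 0; } else { n1 = b; bp1[t] = 1; }
    p0 = n0 + log_emit(0, o);
    p1 = n1 + log_emit(1, o);
  }
  int s = (p1 > p0) ? 1 : 0;
  path[T - 1] = s;
  for (int t = T - 1; t > 0; --t) {
    s = (s == 0) ? bp0[t] : bp1[t];
    path[t - 1] = s;
  }
  return path;
}
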