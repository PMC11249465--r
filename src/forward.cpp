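#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-algorithm log-likelihood for a concatenation of independent
// segments sharing one parameter set.
//
// emis:  T x N state-dependent densities (linear scale)
// tpm:   T x (N*N) row-major transition matrix entries; row t holds the
//        matrix governing the transition from observation t-1 to t (built
//        from the covariates at the step's start). Rows where newseg is
//        true are unused.
// delta: initial state distribution, applied at the start of each segment
// newseg: true where observation t opens a new segment
//
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix emis, NumericMatrix tpm,
                       NumericVector delta, LogicalVector newseg) {
  const int T = emis.nrow(), N = emis.ncol();
  std::vector<double> alpha(N), prev(N);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (newseg[t]) {
      for (int j = 0; j < N; ++j) alpha[j] = delta[j] * emis(t, j);
    } else {
      for (int j = 0; j < N; ++j) {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += prev[i] * tpm(t, i * N + j);
        alpha[j] = s * emis(t, j);
      }
    }
    double c = 0.0;
    for (int j = 0; j < N; ++j) c += alpha[j];
    if (!(c > 0.0) || !R_finite(c)) return R_NegInf;
    ll += std::log(c);
    for (int j = 0; j < N; ++j) prev[j] = alpha[j] / c;
  }
  return ll;
}
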