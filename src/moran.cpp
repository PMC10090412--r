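#include <Rcpp.h>
using namespace Rcpp;

// Frequency-dependent Moran birth-death chain on the count i of the focal
// strategy. Payoffs are supplied as lookup tables over i = 0..N (the expected
// payoff only depends on p = i/N). One generation = N elementary steps.
// Uses R's RNG so set.seed() in R makes runs bit-reproducible.
// [[Rcpp::export]]
IntegerVector moran_chain(NumericVector ev_focal, NumericVector ev_other,
                          int i0, int N, int generations, double intensity,
                          double mutation_rate) {
  if (ev_focal.size() != N + 1 || ev_other.size() != N + 1)
    stop("payoff tables must have length N + 1");
  if (i0 < 0 || i0 > N) stop("initial count out of range");

  IntegerVector counts(generations + 1);
  counts[0] = i0;
  int i = i0;
  RNGScope scope;

  for (int g = 0; g < generations; ++g) {
    for (int s = 0; s < N; ++s) {
      double wf = std::exp(intensity * ev_focal[i]);
      double wo = std::exp(intensity * ev_other[i]);
      double pf_birth = (i * wf) / (i * wf + (N - i) * wo);
      bool birth_focal = unif_rand() < pf_birth;
      if (mutation_rate > 0 && unif_rand() < mutation_rate)
        birth_focal = !birth_focal;
      bool death_focal = unif_rand() < (double)i / N;
      i += (birth_focal ? 1 : 0) - (death_focal ? 1 : 0);
      if (i < 0) i = 0;
      if (i > N) i = N;
    }
    counts[g + 1] = i;
  }
  return counts;
}
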