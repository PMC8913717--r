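#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric sampling by the conditional (chain) method:
// clone i receives rhyper(reads_i, remaining_other, remaining_depth).
// Returns an S x n_rep matrix of downsampled read counts; column sums are
// exactly `depth`. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".downsample_counts_cpp")]]
IntegerMatrix downsample_counts_cpp(NumericVector reads, int depth, int n_rep) {
  const int s = reads.size();
  double total = 0.0;
  for (int i = 0; i < s; ++i) total += reads[i];
  if (depth > total + 1e-9)
    stop("depth exceeds total reads");
  IntegerMatrix out(s, n_rep);
  for (int r = 0; r < n_rep; ++r) {
    double remaining = total;
    int k = depth;
    for (int i = 0; i < s && k > 0; ++i) {
      double m = reads[i];
      double n_other = remaining - m;
      int x = (n_other <= 0.5) ? k : (int) ::Rf_rhyper(m, n_other, (double) k);
      out(i, r) = x;
      k -= x;
      remaining -= m;
    }
  }
  return out;
}
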