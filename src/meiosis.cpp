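#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Batch gamete simulation.
//
// For each requested gamete (one per entry of `parents`, 1-based row index
// into the haplotype matrices) and each chromosome: draw the crossover
// count n_co ~ Poisson(lambda_chr), draw n_co crossover positions
// uniformly on (0, lambda_chr) and sort them, pick the starting strand
// equiprobably, then copy marker h from the strand whose index alternates
// at each crossover; a marker lying exactly on a crossover position starts
// the next segment.  Uses R's RNG so results are reproducible from
// set.seed() and bit-identical to the R reference implementation, which
// consumes the stream in the same order (rpois, runif(n_co), strand draw).
// [[Rcpp::export]]
IntegerMatrix sim_gametes_cpp(const IntegerMatrix& H1,
                              const IntegerMatrix& H2,
                              const IntegerVector& parents,
                              const NumericVector& pos,
                              const IntegerVector& chr_start,
                              const IntegerVector& chr_end,
                              const NumericVector& lambda) {
  const int n_gam = parents.size();
  const int n_snp = H1.ncol();
  const int n_chr = lambda.size();
  IntegerMatrix out(n_gam, n_snp);
  std::vector<double> co;

  for (int g = 0; g < n_gam; ++g) {
    const int p = parents[g] - 1;
    for (int l = 0; l < n_chr; ++l) {
      const double lam = lambda[l];
      const int n_co = (int) R::rpois(lam);
      co.resize(n_co);
      for (int k = 0; k < n_co; ++k) co[k] = R::runif(0.0, lam);
      std::sort(co.begin(), co.end());
      // strand 0 = H1 first, 1 = H2 first
      int strand0 = (unif_rand() < 0.5) ? 0 : 1;
      const int lo = chr_start[l] - 1;   // may be -1 when chromosome empty
      const int hi = chr_end[l] - 1;
      int k = 0;  // crossovers passed (count of co <= marker position)
      for (int h = lo; h >= 0 && h <= hi; ++h) {
        const double ph = pos[h];
        while (k < n_co && co[k] <= ph) ++k;
        const int strand = (strand0 + k) % 2;
        out(g, h) = (strand == 0) ? H1(p, h) : H2(p, h);
      }
    }
  }
  return out;
}
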