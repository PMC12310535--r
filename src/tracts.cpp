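#include <Rcpp.h>
using namespace Rcpp;

// Renewal-coalescent simulation of homozygosity tracts along chromosomes.
//
// The TMRCA t of the two haplotypes at the left chromosome end is drawn from
// the position marginal Exp(rate = lambda), lambda = 1/(2 Ne). Moving right,
// the distance to the next recombination breakpoint is Exp(rate = 2 t) per
// Morgan; at a breakpoint the new TMRCA is drawn from the recombination-rate
// biased law Gamma(shape = 2, rate = lambda), which is exactly the redraw
// that keeps the position marginal Exp(lambda) (and hence the closed-form
// tract density 8*lambda/(2l+lambda)^3) invariant along the chromosome.
// Tracts overlapping a chromosome end are truncated and flagged as not
// interior; interior tracts are delimited by two recombination events.
//
// Lengths are in Morgans; tmrca in generations. Tracts shorter than
// min_len are not recorded (memory guard for large Ne).
// [[Rcpp::export]]
DataFrame sim_tracts_cpp(NumericVector len_morgans, double lambda, int n_ind,
                         double min_len) {
  std::vector<int> ind, chrom;
  std::vector<double> start, end, tmrca;
  std::vector<int> interior;
  const double mean_t = 1.0 / lambda;
  for (int i = 0; i < n_ind; ++i) {
    for (int c = 0; c < len_morgans.size(); ++c) {
      const double L = len_morgans[c];
      double pos = 0.0;
      double t = R::rexp(mean_t);
      bool first = true;
      while (pos < L) {
        double x = R::rexp(1.0 / (2.0 * t));
        double e = pos + x;
        bool trunc = e >= L;
        if (trunc) e = L;
        if (e - pos >= min_len) {
          ind.push_back(i + 1);
          chrom.push_back(c + 1);
          start.push_back(pos);
          end.push_back(e);
          tmrca.push_back(t);
          interior.push_back((!first && !trunc) ? 1 : 0);
        }
        pos = e;
        if (!trunc) t = R::rgamma(2.0, mean_t);
        first = false;
      }
    }
  }
  return DataFrame::create(
      _["individual"] = ind, _["chrom_idx"] = chrom, _["start_M"] = start,
      _["end_M"] = end, _["tmrca"] = tmrca, _["interior"] = interior);
}
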