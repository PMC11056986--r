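#include <Rcpp.h>
using namespace Rcpp;

// Symmetrized KLD between the two pseudocount-regularized histograms of a
// single residue, evaluated for every window of the growing/sliding/shrinking
// scheme. binsA/binsB hold 1-based linear bin indices (shared joint-box
// geometry, K bins total) for N paired snapshots. Bins empty in both
// histograms contribute exactly zero (equal n, K and pseudocount on both
// sides), so sums run over occupied bins only.
// [[Rcpp::export]]
NumericVector windowed_skld_cpp(IntegerVector binsA, IntegerVector binsB,
                                int K, double pseudo,
                                IntegerVector starts, IntegerVector ends) {
  const int N = binsA.size();
  if (binsB.size() != N)
    stop("paired snapshot counts differ");
  const int nw = starts.size();
  NumericVector out(nw);

  std::vector<int> countA(K, 0), countB(K, 0);
  std::vector<int> touched;
  touched.reserve(256);

  for (int w = 0; w < nw; ++w) {
    const int s = starts[w] - 1, e = ends[w] - 1;  // to 0-based, inclusive
    if (s < 0 || e >= N || e < s)
      stop("window bounds out of range");
    const int n = e - s + 1;
    touched.clear();
    for (int f = s; f <= e; ++f) {
      int a = binsA[f] - 1, b = binsB[f] - 1;
      if (a < 0 || a >= K || b < 0 || b >= K)
        stop("bin index outside joint box");
      if (countA[a] == 0 && countB[a] == 0) touched.push_back(a);
      ++countA[a];
      if (countA[b] == 0 && countB[b] == 0) touched.push_back(b);
      ++countB[b];
    }
    const double denom = n + K * pseudo;
    double fwd = 0.0, rev = 0.0;  // fwd: sum q ln(q/p); rev: sum p ln(p/q)
    for (size_t t = 0; t < touched.size(); ++t) {
      const int k = touched[t];
      const double p = (countA[k] + pseudo) / denom;
      const double q = (countB[k] + pseudo) / denom;
      const double lr = std::log(q / p);
      fwd += q * lr;
      rev -= p * lr;
      countA[k] = 0;
      countB[k] = 0;
    }
    out[w] = 0.5 * (fwd + rev);
  }
  return out;
}
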