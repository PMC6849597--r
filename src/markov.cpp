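#include <Rcpp.h>
using namespace Rcpp;

// Order-2 Markov walk over a 4-letter alphabet. `cum` is 16 x 4 of
// cumulative next-base probabilities per dinucleotide context; `init` gives
// the first two states (1-4); `u` supplies one uniform draw per position.
// [[Rcpp::export]]
IntegerVector markov_walk(NumericMatrix cum, IntegerVector init,
                          NumericVector u) {
  const int len = u.size();
  IntegerVector out(len);
  if (len < 2) stop("length must be >= 2");
  out[0] = init[0];
  out[1] = init[1];
  for (int i = 2; i < len; ++i) {
    const int ctx = (out[i - 2] - 1) * 4 + (out[i - 1] - 1);
    const double x = u[i];
    int b = 0;
    while (b < 3 && x > cum(ctx, b)) ++b;
    out[i] = b + 1;
  }
  return out;
}

// Minimum Hamming distance of `oligo` over all ungapped windows of `seq`
// (both as integer-coded character vectors). Returns oligo length + 1 when
// no window fits.
// [[Rcpp::export]]
int min_hamming(IntegerVector oligo, IntegerVector seq) {
  const int L = oligo.size(), n = seq.size();
  if (n < L) return L + 1;
  int best = L;
  for (int off = 0; off + L <= n; ++off) {
    int mm = 0;
    for (int p = 0; p < L && mm < best; ++p) {
      if (oligo[p] != seq[off + p]) ++mm;
    }
    if (mm < best) best = mm;
    if (best == 0) return 0;
  }
  return best;
}
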