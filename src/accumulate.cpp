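#include <Rcpp.h>
using namespace Rcpp;

// Add a tabulated kernel around each fragment centre into a per-base track.
//
// out[x] += beta[i] * kern[x - pos[i] + radius] for every i and every sample
// index x in [0, l) that falls inside the kernel support. Positions are
// 0-based indices of the kernel centre relative to the first track sample;
// they may lie outside [0, l) (fragments just outside the region still
// contribute their overlapping tail). Direct accumulation keeps untouched
// bases at exactly zero, which matters downstream: peak detection must not
// see numerical noise in zero-coverage regions.
// [[Rcpp::export(".accumulateKernel")]]
NumericVector accumulate_kernel(int l, IntegerVector pos, NumericVector beta,
                                NumericVector kern, int radius) {
  if (pos.size() != beta.size())
    stop("positions and weights differ in length");
  if (kern.size() != 2 * radius + 1)
    stop("kernel length must be 2*radius + 1");
  NumericVector out(l);
  int n = pos.size();
  for (int i = 0; i < n; ++i) {
    int p = pos[i];
    double b = beta[i];
    int xlo = p - radius, xhi = p + radius;
    if (xlo < 0) xlo = 0;
    if (xhi > l - 1) xhi = l - 1;
    for (int x = xlo; x <= xhi; ++x)
      out[x] += b * kern[x - p + radius];
  }
  return out;
}
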