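#include <Rcpp.h>

using namespace Rcpp;

// Sliding-window quality trimming: scanning left to right, the read is cut at
// the start of the first window whose mean Phred quality (ASCII offset 33)
// falls below `min_quality`; everything from that window on is removed.
// Reads shorter than the window are left untouched (the length filter applies
// downstream). Returns the kept length for each read.
// [[Rcpp::export(name = ".trim_lengths")]]
IntegerVector trim_lengths(CharacterVector quals, int window, double min_quality) {
  if (window < 1) stop("window must be >= 1");
  IntegerVector out(quals.size());
  for (R_xlen_t r = 0; r < quals.size(); ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    const int len = LENGTH(STRING_ELT(quals, r));
    int keep = len;
    if (len >= window) {
      int sum = 0;
      for (int i = 0; i < window; ++i) sum += q[i] - 33;
      for (int i = 0; ; ++i) {
        if ((double)sum / window < min_quality) { keep = i; break; }
        if (i + window >= len) break;
        sum += (q[i + window] - 33) - (q[i] - 33);
      }
    }
    out[r] = keep;
  }
  return out;
}
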