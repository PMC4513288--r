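#include <Rcpp.h>
using namespace Rcpp;

// Longest contiguous run of bases with Phred strictly above `min_phred`,
// per read. Qualities arrive as Phred+33 ASCII strings. Returns an n x 3
// integer matrix: columns start, end (1-based inclusive; 0,0 if no run of
// at least `min_run`) and run length. Ties broken leftmost.
// [[Rcpp::export(name = ".groom_spans_cpp")]]
IntegerMatrix groom_spans_cpp(CharacterVector quals, int min_phred, int min_run) {
  int n = quals.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int len = LENGTH(STRING_ELT(quals, i));
    int best_len = 0, best_start = -1;
    int run_start = 0, run_len = 0;
    for (int j = 0; j < len; ++j) {
      int phred = (int)(unsigned char)q[j] - 33;
      if (phred > min_phred) {
        if (run_len == 0) run_start = j;
        ++run_len;
        if (run_len > best_len) { best_len = run_len; best_start = run_start; }
      } else {
        run_len = 0;
      }
    }
    if (best_len >= min_run) {
      out(i, 0) = best_start + 1;
      out(i, 1) = best_start + best_len;
      out(i, 2) = best_len;
    } else {
      out(i, 0) = 0; out(i, 1) = 0; out(i, 2) = best_len;
    }
  }
  return out;
}
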