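#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped local segment score between two sequences under an
// ASCII-indexed 128x128 score lookup (built in R from a BLOSUM matrix or a
// match/mismatch scheme). Kadane's scan along every diagonal; segments with
// non-positive best score report 0 with empty spans. Ties broken by smallest
// query start, then smallest subject start.
//
// Returns c(score, qstart, qend, sstart, send), spans 1-based inclusive,
// all zero when the best score is 0.
static void best_segment(const char *q, int lq, const char *s, int ls,
                         const IntegerMatrix &lut, int out[5]) {
  int best = 0, bqs = 0, bqe = 0, bss = 0, bse = 0;
  for (int d = -(lq - 1); d <= ls - 1; ++d) {
    // query position j pairs subject position j + d
    int lo = d < 0 ? -d : 0;
    int hi = std::min(lq, ls - d);
    int cur = 0, seg_start = lo;
    for (int j = lo; j < hi; ++j) {
      int sc = lut((unsigned char)q[j], (unsigned char)s[j + d]);
      if (cur <= 0) { cur = sc; seg_start = j; }
      else cur += sc;
      if (cur > best ||
          (cur == best && best > 0 &&
           (seg_start + 1 < bqs || (seg_start + 1 == bqs && seg_start + d + 1 < bss)))) {
        best = cur; bqs = seg_start + 1; bqe = j + 1;
        bss = seg_start + d + 1; bse = j + d + 1;
      }
    }
  }
  out[0] = best; out[1] = bqs; out[2] = bqe; out[3] = bss; out[4] = bse;
}

// [[Rcpp::export(name = ".local_segment_cpp")]]
IntegerVector local_segment_cpp(std::string query, std::string subject,
                                IntegerMatrix lut) {
  int out[5];
  best_segment(query.c_str(), query.size(), subject.c_str(), subject.size(), lut, out);
  return IntegerVector::create(out[0], out[1], out[2], out[3], out[4]);
}

// Vectorized form: one query against many subjects. Returns n x 5 matrix.
// [[Rcpp::export(name = ".local_segment_many_cpp")]]
IntegerMatrix local_segment_many_cpp(std::string query, CharacterVector subjects,
                                     IntegerMatrix lut) {
  int n = subjects.size();
  IntegerMatrix res(n, 5);
  const char *q = query.c_str();
  int lq = query.size();
  int out[5];
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(subjects, i));
    int ls = LENGTH(STRING_ELT(subjects, i));
    best_segment(q, lq, s, ls, lut, out);
    for (int j = 0; j < 5; ++j) res(i, j) = out[j];
  }
  return res;
}
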