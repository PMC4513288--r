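#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// 2-bit rolling k-mer codes for each sequence (k <= 15 so codes fit a signed
// 32-bit integer). Windows containing a non-ACGT base are NA. Used by the
// walking read index, where integer keys keep the postings table compact.
// [[Rcpp::export(name = ".kmer_codes_cpp")]]
List kmer_codes_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 15) stop("k must be in [1, 15]");
  int n = seqs.size();
  List out(n);
  uint32_t mask = (1u << (2 * k)) - 1u;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    int nk = len - k + 1;
    if (nk < 1) { out[i] = IntegerVector(0); continue; }
    IntegerVector codes(nk);
    uint32_t code = 0;
    int run = 0;
    for (int j = 0; j < len; ++j) {
      int b = base_code2(s[j]);
      if (b < 0) { run = 0; code = 0; }
      else { code = ((code << 2) | (uint32_t)b) & mask; ++run; }
      if (j >= k - 1) codes[j - k + 1] = (run >= k) ? (int)code : NA_INTEGER;
    }
    out[i] = codes;
  }
  return out;
}
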