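#include <Rcpp.h>
using namespace Rcpp;

// Apply single-base substitutions: for each i, set seqs[idx[i]][pos[i]] = base[i].
// idx and pos are 1-based. Used by the read simulator's error model.
// [[Rcpp::export(name = ".mutate_bases_cpp")]]
CharacterVector mutate_bases_cpp(CharacterVector seqs, IntegerVector idx,
                                 IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  int n = idx.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(out[idx[i] - 1]);
    int p = pos[i] - 1;
    if (p < 0 || p >= (int)s.size()) stop("substitution position out of range");
    s[p] = as<std::string>(base[i])[0];
    out[idx[i] - 1] = s;
  }
  return out;
}

// Pairwise mismatch counts between equal-length string pairs a[i], b[i].
// [[Rcpp::export(name = ".count_mismatches_cpp")]]
IntegerVector count_mismatches_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i));
    if (LENGTH(STRING_ELT(b, i)) != la) stop("unequal string lengths at pair");
    int m = 0;
    for (int j = 0; j < la; ++j) if (x[j] != y[j]) ++m;
    out[i] = m;
  }
  return out;
}

// Encode a matrix of Phred scores (rows = reads) as Phred+33 ASCII strings.
// [[Rcpp::export(name = ".phred_rows_to_ascii_cpp")]]
CharacterVector phred_rows_to_ascii_cpp(IntegerMatrix q) {
  int n = q.nrow(), m = q.ncol();
  CharacterVector out(n);
  std::string buf(m, ' ');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int v = q(i, j);
      if (v < 0) v = 0;
      if (v > 60) v = 60;
      buf[j] = (char)(v + 33);
    }
    out[i] = buf;
  }
  return out;
}
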