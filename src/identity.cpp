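#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int> encode(const char *s, int len) {
  std::vector<int> v(len);
  for (int i = 0; i < len; ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp(const std::vector<int> &v) {
  int n = v.size();
  std::vector<int> r(n);
  for (int i = 0; i < n; ++i) r[i] = v[n - 1 - i] < 0 ? -1 : 3 - v[n - 1 - i];
  return r;
}

// identical-base count for read placed so read[0] pairs transcript[d]
static int diag_identity(const std::vector<int> &rd, const std::vector<int> &tr, int d) {
  int lo = d < 0 ? -d : 0;
  int hi = std::min((int)rd.size(), (int)tr.size() - d);
  int m = 0;
  for (int j = lo; j < hi; ++j)
    if (rd[j] >= 0 && rd[j] == tr[j + d]) ++m;
  return m;
}

// Exhaustive max identical-base count over every ungapped offset of the read
// (forward and reverse complement) against the transcript. Offsets that hang
// off either end are compared over the overlap only.
// [[Rcpp::export(name = ".best_identity_cpp")]]
int best_identity_cpp(std::string read, std::string transcript) {
  std::vector<int> tr = encode(transcript.c_str(), transcript.size());
  std::vector<int> fwd = encode(read.c_str(), read.size());
  std::vector<int> rev = revcomp(fwd);
  int lr = fwd.size(), lt = tr.size();
  int best = 0;
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int> &r = strand == 0 ? fwd : rev;
    for (int d = -(lr - 1); d <= lt - 1; ++d) {
      int m = diag_identity(r, tr, d);
      if (m > best) best = m;
    }
  }
  return best;
}

// Seed-and-verify screen: for each read, does some ungapped placement on the
// transcript (either strand) reach >= min_identity identical bases?  A k=9
// exact seed is guaranteed for any qualifying placement when min_identity >=
// 90 and reads are <= 100 nt (>= 90 matching bases broken into at most 11
// runs leaves a run of >= 9), so the screen is exact above threshold.
// [[Rcpp::export(name = ".reads_match_cpp")]]
LogicalVector reads_match_cpp(CharacterVector reads, std::string transcript,
                              int min_identity, int k) {
  std::vector<int> tr = encode(transcript.c_str(), transcript.size());
  int lt = tr.size();
  std::unordered_map<uint32_t, std::vector<int>> idx;
  if (lt >= k) {
    uint32_t code = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int run = 0;
    for (int i = 0; i < lt; ++i) {
      if (tr[i] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)tr[i]) & mask;
      if (++run >= k) idx[code].push_back(i - k + 1);
    }
  }
  int n = reads.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (len < min_identity) { out[i] = false; continue; }
    std::vector<int> fwd = encode(s, len);
    bool hit = false;
    for (int strand = 0; strand < 2 && !hit; ++strand) {
      std::vector<int> rd = strand == 0 ? fwd : revcomp(fwd);
      std::unordered_set<int> diags;
      uint32_t code = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
      int run = 0;
      for (int j = 0; j < len && !hit; ++j) {
        if (rd[j] < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)rd[j]) & mask;
        if (++run < k) continue;
        int rp = j - k + 1;
        auto it = idx.find(code);
        if (it == idx.end()) continue;
        for (int tp : it->second) {
          int d = tp - rp;
          if (diags.insert(d).second) {
            if (diag_identity(rd, tr, d) >= min_identity) { hit = true; break; }
          }
        }
      }
    }
    out[i] = hit;
  }
  return out;
}
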