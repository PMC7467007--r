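// Seed-and-extend contaminant screen: exact 2-bit seeds anchor candidate
// diagonals, which are verified by Hamming distance against a mismatch budget
// of floor(max_mismatch_frac * read_length). Both read strands are tried.
// When the read is too short to guarantee budget+1 disjoint seeds the screen
// falls back to a full sliding Hamming scan, so the decision is always exact.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstring>
#include <cstdint>
#include <string>
using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> SeedIndex;

static bool encode_window(const char *s, int pos, int k, uint64_t *key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  *key = v;
  return true;
}

static inline bool hamming_le(const char *a, const char *b, int len, int budget) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (toupper(a[i]) != toupper(b[i]) && ++mm > budget) return false;
  }
  return true;
}

// returns 1-based index of first matching reference, or 0
static int match_read(const std::string &read,
                      const std::vector<std::string> &refs,
                      const SeedIndex &index, int seed_len, double frac) {
  int len = (int)read.size();
  int budget = (int)(frac * len);
  const char *r = read.c_str();

  bool seeded = seed_len >= 8 && len >= seed_len * (budget + 1);
  if (seeded) {
    // budget+1 disjoint seeds guarantee one exact seed at <= budget mismatches
    std::vector<int> seed_pos;
    for (int p = 0; p + seed_len <= len; p += seed_len) seed_pos.push_back(p);
    if (seed_pos.back() != len - seed_len) seed_pos.push_back(len - seed_len);
    std::unordered_set<uint64_t> tried;  // (ref << 32) | offset, offsets < 2^32
    for (int p : seed_pos) {
      uint64_t key;
      if (!encode_window(r, p, seed_len, &key)) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (const auto &hit : it->second) {
        int ref_i = hit.first;
        long off = (long)hit.second - p;
        if (off < 0 || off + len > (long)refs[ref_i].size()) continue;
        uint64_t sig = ((uint64_t)ref_i << 40) | (uint64_t)off;
        if (!tried.insert(sig).second) continue;
        if (hamming_le(r, refs[ref_i].c_str() + off, len, budget))
          return ref_i + 1;
      }
    }
    return 0;
  }
  // exhaustive fallback
  for (size_t ref_i = 0; ref_i < refs.size(); ++ref_i) {
    const std::string &ref = refs[ref_i];
    if ((int)ref.size() < len) continue;
    for (size_t off = 0; off + len <= ref.size(); ++off) {
      if (hamming_le(r, ref.c_str() + off, len, budget)) return (int)ref_i + 1;
    }
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector cpp_screen(CharacterVector reads, CharacterVector refs,
                         int seed_len, double max_mismatch_frac) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 0.1)
    stop("max_mismatch_frac must be in [0, 0.1)");
  std::vector<std::string> ref_str;
  ref_str.reserve(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i)
    ref_str.push_back(std::string(CHAR(STRING_ELT(refs, i))));

  SeedIndex index;
  for (size_t i = 0; i < ref_str.size(); ++i) {
    const char *s = ref_str[i].c_str();
    int n = (int)ref_str[i].size();
    for (int p = 0; p + seed_len <= n; ++p) {
      uint64_t key;
      if (encode_window(s, p, seed_len, &key))
        index[key].push_back({(int)i, p});
    }
  }

  R_xlen_t n_reads = reads.size();
  IntegerVector out(n_reads);
  for (R_xlen_t i = 0; i < n_reads; ++i) {
    std::string fwd(CHAR(STRING_ELT(reads, i)));
    int m = match_read(fwd, ref_str, index, seed_len, max_mismatch_frac);
    if (m == 0) {
      std::string rc(fwd.size(), 'N');
      for (size_t j = 0; j < fwd.size(); ++j)
        rc[j] = comp_base(fwd[fwd.size() - 1 - j]);
      m = match_read(rc, ref_str, index, seed_len, max_mismatch_frac);
    }
    out[i] = m;
  }
  return out;
}
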