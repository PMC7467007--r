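// Canonical k-mer counting, spectrum histograms and duplicated-k-mer masking.
// K-mers are 2-bit packed: into a 64-bit integer for k <= 31 and a 128-bit
// integer above that (k up to 63; the analyses use k = 21 and k = 57).
// Windows containing non-ACGT bases are skipped.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cstring>
#include <string>
using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

struct KeyHash {
  size_t operator()(const uint64_t &x) const {
    uint64_t h = x;
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
    return (size_t)h;
  }
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo;
    h ^= hi + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
    return (size_t)h;
  }
};

template <typename UINT>
using KmerMap = std::unordered_map<UINT, uint32_t, KeyHash>;

static void check_k(int k) {
  if (k < 1 || k > 63) stop("k must be between 1 and 63");
}

// Call fn(key, start_position) for every valid k-mer window of s.
template <typename UINT, typename F>
static void scan_kmers(const char *s, size_t n, int k, bool canonical, F fn) {
  if ((size_t)k > n) return;
  const UINT one = 1;
  const UINT mask = (k == 4 * (int)sizeof(UINT) / 1) ? (UINT)~(UINT)0
                                                     : ((one << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  UINT fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (UINT)c) & mask;
    rev = (rev >> 2) | (((UINT)(3 - c)) << shift);
    if (++run >= k) {
      UINT key = fwd;
      if (canonical && rev < fwd) key = rev;
      fn(key, i + 1 - (size_t)k);
    }
  }
}

template <typename UINT>
static std::string decode_kmer(UINT key, int k) {
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = CODE2BASE[(int)(key & 3)];
    key >>= 2;
  }
  return out;
}

template <typename UINT>
static UINT encode_kmer(const char *s, int k, bool canonical, bool *ok) {
  const UINT one = 1;
  const UINT mask = (one << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  UINT fwd = 0, rev = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { *ok = false; return 0; }
    fwd = ((fwd << 2) | (UINT)c) & mask;
    rev = (rev >> 2) | (((UINT)(3 - c)) << shift);
  }
  *ok = true;
  return (canonical && rev < fwd) ? rev : fwd;
}

template <typename UINT>
static void count_into(const CharacterVector &seqs, int k, bool canonical,
                       KmerMap<UINT> &counts) {
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(s);
    scan_kmers<UINT>(s, n, k, canonical,
                     [&](UINT key, size_t) { ++counts[key]; });
  }
}

template <typename UINT>
static List kmer_table_impl(const CharacterVector &seqs, int k, bool canonical) {
  KmerMap<UINT> counts;
  count_into<UINT>(seqs, k, canonical, counts);
  R_xlen_t n = (R_xlen_t)counts.size();
  CharacterVector kmers(n);
  IntegerVector cnt(n);
  R_xlen_t i = 0;
  for (const auto &kv : counts) {
    kmers[i] = decode_kmer<UINT>(kv.first, k);
    cnt[i] = (int)kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// [[Rcpp::export]]
List cpp_kmer_table(CharacterVector seqs, int k, bool canonical) {
  check_k(k);
  if (k <= 31) return kmer_table_impl<uint64_t>(seqs, k, canonical);
  return kmer_table_impl<u128>(seqs, k, canonical);
}

template <typename UINT>
static NumericVector kmer_spectrum_impl(const CharacterVector &seqs, int k,
                                        bool canonical, int max_depth) {
  KmerMap<UINT> counts;
  counts.reserve(1 << 20);
  count_into<UINT>(seqs, k, canonical, counts);
  NumericVector hist(max_depth);
  for (const auto &kv : counts) {
    int d = (int)kv.second;
    if (d > max_depth) d = max_depth;
    hist[d - 1] += 1.0;
  }
  return hist;
}

// Distinct k-mers per depth; depths > max_depth pooled into the last bin.
// [[Rcpp::export]]
NumericVector cpp_kmer_spectrum(CharacterVector seqs, int k, bool canonical,
                                int max_depth) {
  check_k(k);
  if (max_depth < 1) stop("max_depth must be >= 1");
  if (k <= 31) return kmer_spectrum_impl<uint64_t>(seqs, k, canonical, max_depth);
  return kmer_spectrum_impl<u128>(seqs, k, canonical, max_depth);
}

template <typename UINT>
static void mask_positions(const CharacterVector &assembly,
                           const KmerMap<UINT> &asm_counts,
                           const KmerMap<UINT> &read_counts, int k,
                           double band_lo, double band_hi, int copies,
                           std::vector<int> &out_seq, std::vector<int> &out_pos) {
  for (R_xlen_t i = 0; i < assembly.size(); ++i) {
    const char *s = CHAR(STRING_ELT(assembly, i));
    size_t n = strlen(s);
    scan_kmers<UINT>(s, n, k, true, [&](UINT key, size_t pos) {
      auto ac = asm_counts.find(key);
      if (ac == asm_counts.end() || (int)ac->second != copies) return;
      auto rc = read_counts.find(key);
      double d = (rc == read_counts.end()) ? 0.0 : (double)rc->second;
      if (d < band_lo || d > band_hi) return;
      out_seq.push_back((int)i + 1);
      out_pos.push_back((int)pos);
    });
  }
}

template <typename UINT>
static DataFrame kmer_mask_impl(const CharacterVector &assembly,
                                const CharacterVector &reads, int k,
                                double band_lo, double band_hi, int copies) {
  KmerMap<UINT> asm_counts;
  count_into<UINT>(assembly, k, true, asm_counts);
  KmerMap<UINT> read_counts;
  read_counts.reserve(asm_counts.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    size_t n = strlen(s);
    scan_kmers<UINT>(s, n, k, true, [&](UINT key, size_t) {
      auto it = asm_counts.find(key);
      if (it != asm_counts.end()) ++read_counts[key];
    });
  }
  std::vector<int> out_seq, out_pos;
  mask_positions<UINT>(assembly, asm_counts, read_counts, k, band_lo, band_hi,
                       copies, out_seq, out_pos);
  return DataFrame::create(_["seq"] = wrap(out_seq), _["start"] = wrap(out_pos));
}

// Mask of assembly positions whose k-mer occurs exactly `copies` times in the
// assembly and whose read-set depth falls inside [band_lo, band_hi]. Read
// k-mer counting is restricted to k-mers present in the assembly, which keeps
// memory proportional to assembly size rather than read yield.
// [[Rcpp::export]]
DataFrame cpp_kmer_mask(CharacterVector assembly, CharacterVector reads, int k,
                        double band_lo, double band_hi, int copies) {
  check_k(k);
  if (k <= 31)
    return kmer_mask_impl<uint64_t>(assembly, reads, k, band_lo, band_hi, copies);
  return kmer_mask_impl<u128>(assembly, reads, k, band_lo, band_hi, copies);
}

template <typename UINT>
static DataFrame kmer_mask_counts_impl(const CharacterVector &assembly,
                                       const CharacterVector &kmers,
                                       const NumericVector &kmer_depth, int k,
                                       double band_lo, double band_hi,
                                       int copies) {
  KmerMap<UINT> asm_counts;
  count_into<UINT>(assembly, k, true, asm_counts);
  KmerMap<UINT> read_counts;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)strlen(s) != k) stop("k-mer table entries must have length k");
    bool ok = false;
    UINT key = encode_kmer<UINT>(s, k, true, &ok);
    if (!ok) stop("k-mer table entries must be ACGT only");
    read_counts[key] += (uint32_t)kmer_depth[i];
  }
  std::vector<int> out_seq, out_pos;
  mask_positions<UINT>(assembly, asm_counts, read_counts, k, band_lo, band_hi,
                       copies, out_seq, out_pos);
  return DataFrame::create(_["seq"] = wrap(out_seq), _["start"] = wrap(out_pos));
}

// Same mask, but with read k-mer depths supplied as an explicit table.
// [[Rcpp::export]]
DataFrame cpp_kmer_mask_counts(CharacterVector assembly, CharacterVector kmers,
                               NumericVector kmer_depth, int k, double band_lo,
                               double band_hi, int copies) {
  check_k(k);
  if (kmers.size() != kmer_depth.size()) stop("kmer/depth length mismatch");
  if (k <= 31)
    return kmer_mask_counts_impl<uint64_t>(assembly, kmers, kmer_depth, k,
                                           band_lo, band_hi, copies);
  return kmer_mask_counts_impl<u128>(assembly, kmers, kmer_depth, k, band_lo,
                                     band_hi, copies);
}
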