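// Aggregated pileup: per reference position, counts of A/C/G/T from bases
// passing the base-quality threshold on reads passing the mapping-quality
// threshold. Reads must be supplied in reference orientation (the R wrapper
// reverse-complements minus-strand reads first).
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline int base_row(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_pileup(IntegerVector ref_lengths, IntegerVector read_ref,
                IntegerVector read_start, CharacterVector read_seq,
                CharacterVector read_qual, IntegerVector mapq, int min_bq,
                int min_mq) {
  int n_ref = ref_lengths.size();
  R_xlen_t n_reads = read_ref.size();
  if (read_start.size() != n_reads || read_seq.size() != n_reads ||
      read_qual.size() != n_reads || mapq.size() != n_reads)
    stop("alignment columns have unequal lengths");

  std::vector<IntegerMatrix> mats;
  mats.reserve(n_ref);
  for (int r = 0; r < n_ref; ++r) mats.push_back(IntegerMatrix(4, ref_lengths[r]));

  for (R_xlen_t i = 0; i < n_reads; ++i) {
    if (mapq[i] < min_mq) continue;
    int r = read_ref[i] - 1;
    if (r < 0 || r >= n_ref) stop("alignment references unknown sequence");
    const char *s = CHAR(STRING_ELT(read_seq, i));
    const char *q = CHAR(STRING_ELT(read_qual, i));
    int len = (int)strlen(s);
    if ((int)strlen(q) != len) stop("read and quality strings differ in length");
    int start = read_start[i];
    if (start < 0 || start + len > ref_lengths[r])
      stop("alignment beyond reference bounds");
    int *m = INTEGER(mats[r]);
    for (int j = 0; j < len; ++j) {
      if ((int)q[j] - 33 < min_bq) continue;
      int row = base_row(s[j]);
      if (row < 0) continue;
      m[4 * (start + j) + row] += 1;
    }
  }
  List out(n_ref);
  for (int r = 0; r < n_ref; ++r) out[r] = mats[r];
  return out;
}
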