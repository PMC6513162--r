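#pragma once

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>
#include <climits>

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

inline std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': out[i] = 'T'; break;
    case 'C': out[i] = 'G'; break;
    case 'G': out[i] = 'C'; break;
    case 'T': out[i] = 'A'; break;
    default:  out[i] = 'N';
    }
  }
  return out;
}

// Result of a banded pairwise alignment (global in the query, free leading /
// trailing gaps in the reference, optional trailing soft clip of the query
// once the reference is exhausted).
struct PairAln {
  bool ok = false;
  int score = INT_MIN / 4;
  int edit = -1;       // mismatches + gap bases over the aligned part
  int ref_start = -1;  // 0-based leftmost reference position
  int clip = 0;        // trailing soft-clipped query bases
  std::string cigar;
};

PairAln banded_affine(const std::string &q, const std::string &s, int diag,
                      int band, int clip_max);

// Unit-cost edit distance restricted to |i - j| <= band; returns band + 1
// when the true distance exceeds the band (exact otherwise).
int banded_edit(const std::string &a, const std::string &b, int band);

// Full (unbanded) unit-cost Levenshtein distance.
int edit_distance_full(const std::string &a, const std::string &b);

// Left-align an indel against a reference sequence (VCF convention: alleles
// share a leading anchor base). anchor0 is the 0-based position of the
// anchor base; ref_a/alt_a are modified in place.
void left_normalize(const std::string &refseq, int &anchor0, std::string &ref_a,
                    std::string &alt_a);
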