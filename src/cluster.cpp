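// Greedy centroid clustering of dereplicated reads. Sequences arrive sorted
// by (length desc, count desc, sequence asc); each either joins the first
// existing centroid at identity >= threshold (identity = 1 - edits /
// max(len_a, len_b)) or founds a new cluster, subject to an abundance floor
// for founding. An exact-by-pigeonhole shared-k-mer prefilter restricts the
// centroids that must be checked: if identity(q, c) >= t then q and c share
// at least one k-mer for k <= min_len / (floor((1 - t) * max_len) + 1).

#include "common.h"
#include <unordered_map>
using namespace Rcpp;

static inline bool encode_kmer(const std::string &s, int pos, int k,
                               uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_idx(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, IntegerVector counts,
                        double threshold, int min_count) {
  const int n = seqs.size();
  IntegerVector cluster(n, NA_INTEGER);
  NumericVector identity(n, NA_REAL);
  std::vector<std::string> S(n);
  int lmax = 0, lmin = INT_MAX;
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    lmax = std::max(lmax, (int)S[i].size());
    lmin = std::min(lmin, (int)S[i].size());
  }
  if (n == 0)
    return List::create(_["cluster"] = cluster, _["identity"] = identity,
                        _["centroid_idx"] = IntegerVector(0));

  const int emax = (int)std::floor((1.0 - threshold) * lmax + 1e-9);
  int k = lmin / (emax + 1);
  if (k > 31) k = 31;
  const bool brute = (k < 5);

  std::vector<int> centroid_idx; // input index of each centroid, founding order
  std::unordered_map<uint64_t, std::vector<int>> kindex; // kmer -> centroid ids
  std::vector<int> cand_mark; // per-centroid stamp to dedupe candidates
  int stamp = 0;
  std::vector<int> cand;

  for (int i = 0; i < n; ++i) {
    const std::string &q = S[i];
    const int lq = (int)q.size();
    cand.clear();
    if (brute) {
      for (int c = 0; c < (int)centroid_idx.size(); ++c) cand.push_back(c);
    } else {
      ++stamp;
      const int nk = lq - k + 1;
      for (int p = 0; p < nk; ++p) {
        uint64_t key;
        if (!encode_kmer(q, p, k, key)) continue;
        auto it = kindex.find(key);
        if (it == kindex.end()) continue;
        for (int c : it->second) {
          if (cand_mark[c] != stamp) { cand_mark[c] = stamp; cand.push_back(c); }
        }
      }
      std::sort(cand.begin(), cand.end()); // founding order
    }
    int assigned = -1;
    double best_id = NA_REAL;
    for (int c : cand) {
      const std::string &cs = S[centroid_idx[c]];
      const int lc = (int)cs.size();
      const int lm = std::max(lq, lc);
      const int epair = (int)std::floor((1.0 - threshold) * lm + 1e-9);
      if (std::abs(lq - lc) > epair) continue;
      const int d = banded_edit(q, cs, epair);
      if (d <= epair) {
        assigned = c;
        best_id = 1.0 - (double)d / lm;
        break;
      }
    }
    if (assigned >= 0) {
      cluster[i] = assigned + 1;
      identity[i] = best_id;
    } else if (counts[i] >= min_count) {
      const int cid = (int)centroid_idx.size();
      centroid_idx.push_back(i);
      cluster[i] = cid + 1;
      identity[i] = 1.0;
      if (!brute) {
        cand_mark.push_back(0);
        const int nk = lq - k + 1;
        for (int p = 0; p < nk; ++p) {
          uint64_t key;
          if (encode_kmer(q, p, k, key)) kindex[key].push_back(cid);
        }
      }
    }
  }
  IntegerVector cidx(centroid_idx.size());
  for (size_t c = 0; c < centroid_idx.size(); ++c) cidx[c] = centroid_idx[c] + 1;
  return List::create(_["cluster"] = cluster, _["identity"] = identity,
                      _["centroid_idx"] = cidx);
}

// [[Rcpp::export]]
CharacterVector cpp_seq_hash(CharacterVector seqs) {
  // FNV-1a 64-bit, hex-encoded: a stable content hash for cluster tables
  CharacterVector out(seqs.size());
  char buf[17];
  for (int i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    uint64_t h = 1469598103934665603ULL;
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)*p;
      h *= 1099511628211ULL;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
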