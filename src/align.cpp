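// k-mer seeded read mapping against the mock reference, plus pileup
// accumulation. Seeds vote for (centroid, diagonal) candidates; candidates
// are verified either by a Hamming fast path (when the best diagonal already
// explains the read with few mismatches) or by the banded affine DP.
// Reads whose best alignment is tied across more than one centroid are
// reported unmapped (unique-mapping policy).

#include "common.h"
#include <unordered_map>
#include <map>
using namespace Rcpp;

struct KIndex {
  int k = 0;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
  long npos = 0;
  int skipped = 0; // sequences shorter than k
};

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
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KIndex> ptr(new KIndex(), true);
  ptr->k = k;
  ptr->seqs.resize(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    ptr->seqs[i] = as<std::string>(seqs[i]);
    const std::string &s = ptr->seqs[i];
    if ((int)s.size() < k) { ptr->skipped++; continue; }
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s, p, k, key)) continue;
      ptr->map[key].push_back(std::make_pair(i, p));
      ptr->npos++;
    }
  }
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<KIndex> ptr(xp);
  return List::create(_["k"] = ptr->k, _["n_seqs"] = (int)ptr->seqs.size(),
                      _["n_positions"] = (double)ptr->npos,
                      _["n_kmers"] = (double)ptr->map.size(),
                      _["n_skipped"] = ptr->skipped);
}

struct Cand {
  int ref; int diag; int votes; char strand;
};

struct AlnOut {
  bool ok = false;
  int ref = -1, pos = -1, edit = -1, score = INT_MIN / 4, votes = 0;
  char strand = '+';
  std::string cigar;
};

static void gather_candidates(const KIndex &ix, const std::string &qs,
                              char strand, int stride,
                              std::vector<Cand> &out) {
  const int n = (int)qs.size(), k = ix.k;
  if (n < k) return;
  std::map<std::pair<int, int>, int> votes; // (ref, diag) -> count
  int p = 0;
  while (true) {
    uint64_t key;
    if (encode_kmer(qs, p, k, key)) {
      auto it = ix.map.find(key);
      if (it != ix.map.end()) {
        for (auto &hit : it->second)
          votes[std::make_pair(hit.first, hit.second - p)]++;
      }
    }
    if (p == n - k) break;
    p = std::min(p + stride, n - k);
  }
  // one candidate per reference: the most-voted diagonal
  int cur_ref = -1; Cand best; int tot = 0;
  auto flush = [&]() {
    if (cur_ref >= 0) { best.votes = tot; out.push_back(best); }
  };
  for (auto &kv : votes) {
    const int ref = kv.first.first, diag = kv.first.second, v = kv.second;
    if (ref != cur_ref) {
      flush();
      cur_ref = ref; tot = 0;
      best.ref = ref; best.diag = diag; best.votes = v; best.strand = strand;
    } else if (v > best.votes ||
               (v == best.votes && std::abs(diag) < std::abs(best.diag))) {
      best.diag = diag; best.votes = v;
    }
    tot += v;
  }
  flush();
}

static AlnOut eval_candidate(const KIndex &ix, const std::string &qs,
                             const Cand &c, int band, int fast_max,
                             int max_edit) {
  AlnOut r;
  const std::string &ref = ix.seqs[c.ref];
  const int n = (int)qs.size(), m = (int)ref.size();
  // Hamming fast path at the anchor diagonal
  if (c.diag >= 0 && c.diag + n <= m) {
    int h = 0;
    for (int i = 0; i < n && h <= fast_max; ++i)
      if (qs[i] != ref[c.diag + i]) h++;
    if (h <= fast_max && h <= max_edit) {
      r.ok = true; r.ref = c.ref; r.pos = c.diag; r.edit = h;
      r.score = n - 2 * h; r.votes = c.votes; r.strand = c.strand;
      r.cigar = std::to_string(n) + "M";
      return r;
    }
  }
  PairAln a = banded_affine(qs, ref, c.diag, band, band);
  if (a.ok && a.edit <= max_edit) {
    r.ok = true; r.ref = c.ref; r.pos = a.ref_start; r.edit = a.edit;
    r.score = a.score; r.votes = c.votes; r.strand = c.strand;
    r.cigar = a.cigar;
  }
  return r;
}

// [[Rcpp::export]]
List cpp_align_reads(SEXP xp, CharacterVector reads, double max_mm_frac,
                     int band, int fast_max, int stride, int max_cand) {
  XPtr<KIndex> ptr(xp);
  const KIndex &ix = *ptr;
  const int nr = reads.size();
  IntegerVector ref(nr, NA_INTEGER), pos(nr, NA_INTEGER), edit(nr, NA_INTEGER);
  CharacterVector cigar(nr, NA_STRING), strand(nr, NA_STRING);
  std::vector<Cand> cands;
  std::vector<AlnOut> res;
  for (int i = 0; i < nr; ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int n = (int)q.size();
    if (n < ix.k) continue;
    const int max_edit = (int)std::floor(max_mm_frac * n + 1e-9);
    cands.clear();
    gather_candidates(ix, q, '+', stride, cands);
    const std::string qrc = revcomp_str(q);
    gather_candidates(ix, qrc, '-', stride, cands);
    if (cands.empty()) continue;
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand &a, const Cand &b) {
                       if (a.votes != b.votes) return a.votes > b.votes;
                       if (a.ref != b.ref) return a.ref < b.ref;
                       return a.strand < b.strand; // '+' before '-'
                     });
    if ((int)cands.size() > max_cand) cands.resize(max_cand);
    res.clear();
    for (auto &c : cands) {
      AlnOut r = eval_candidate(ix, c.strand == '+' ? q : qrc, c, band,
                                fast_max, max_edit);
      if (r.ok) res.push_back(r);
    }
    if (res.empty()) continue;
    std::stable_sort(res.begin(), res.end(), [](const AlnOut &a, const AlnOut &b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.edit != b.edit) return a.edit < b.edit;
      if (a.votes != b.votes) return a.votes > b.votes;
      if (a.ref != b.ref) return a.ref < b.ref;
      return a.strand < b.strand;
    });
    const AlnOut &top = res[0];
    if (res.size() > 1) {
      const AlnOut &second = res[1];
      if (second.score == top.score && second.edit == top.edit &&
          second.ref != top.ref)
        continue; // ambiguous: equally good on >1 centroid
    }
    ref[i] = top.ref + 1;
    pos[i] = top.pos;
    edit[i] = top.edit;
    cigar[i] = top.cigar;
    strand[i] = std::string(1, top.strand);
  }
  return List::create(_["ref"] = ref, _["pos0"] = pos, _["cigar"] = cigar,
                      _["strand"] = strand, _["edit"] = edit);
}

// [[Rcpp::export]]
List cpp_make_pileup(CharacterVector refs, CharacterVector reads,
                     IntegerVector ref1, IntegerVector pos0,
                     CharacterVector cigars, CharacterVector strands,
                     IntegerVector ind1, int n_ind) {
  const int nref = refs.size(), nr = reads.size();
  std::vector<std::string> R(nref);
  std::vector<int> L(nref);
  List counts(nref), pooled(nref), maxind(nref);
  std::vector<int *> cptr(nref);
  for (int r = 0; r < nref; ++r) {
    R[r] = as<std::string>(refs[r]);
    L[r] = (int)R[r].size();
    IntegerVector v(4 * L[r] * n_ind, 0); // dim (4, L, n_ind), set in R
    counts[r] = v;
    cptr[r] = INTEGER(v);
  }
  // indel alleles keyed (ref, anchor, ref_allele, alt_allele, ind)
  std::map<std::tuple<int, int, std::string, std::string, int>, int> idl;
  long rejected = 0;
  for (int i = 0; i < nr; ++i) {
    if (IntegerVector::is_na(ref1[i])) continue;
    const int r = ref1[i] - 1, ind = ind1[i] - 1;
    if (r < 0 || r >= nref || ind < 0 || ind >= n_ind) { rejected++; continue; }
    std::string seq = as<std::string>(reads[i]);
    if (as<std::string>(strands[i]) == "-") seq = revcomp_str(seq);
    const std::string &cg = as<std::string>(cigars[i]);
    // bounds pre-check
    {
      int j = pos0[i];
      size_t p = 0;
      bool bad = (j < 0);
      int qlen = 0;
      while (p < cg.size() && !bad) {
        int len = 0;
        while (p < cg.size() && isdigit(cg[p])) len = len * 10 + (cg[p++] - '0');
        char op = cg[p++];
        if (op == 'M') { j += len; qlen += len; }
        else if (op == 'D') j += len;
        else if (op == 'I' || op == 'S') qlen += len;
        else bad = true;
      }
      if (bad || j > L[r] || qlen != (int)seq.size()) { rejected++; continue; }
    }
    int qi = 0, j = pos0[i];
    size_t p = 0;
    int *cc = cptr[r];
    while (p < cg.size()) {
      int len = 0;
      while (p < cg.size() && isdigit(cg[p])) len = len * 10 + (cg[p++] - '0');
      char op = cg[p++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int b = base_idx(seq[qi + t]);
          if (b >= 0) cc[b + 4 * ((j + t) + (size_t)L[r] * ind)]++;
        }
        qi += len; j += len;
      } else if (op == 'I') {
        if (j >= 1) {
          int anchor = j - 1;
          std::string ra(1, R[r][anchor]);
          std::string aa = ra + seq.substr(qi, len);
          left_normalize(R[r], anchor, ra, aa);
          idl[std::make_tuple(r, anchor, ra, aa, ind)]++;
        }
        qi += len;
      } else if (op == 'D') {
        if (j >= 1) {
          int anchor = j - 1;
          std::string ra = R[r].substr(anchor, len + 1);
          std::string aa(1, R[r][anchor]);
          left_normalize(R[r], anchor, ra, aa);
          idl[std::make_tuple(r, anchor, ra, aa, ind)]++;
        }
        j += len;
      } else if (op == 'S') {
        qi += len;
      }
    }
  }
  for (int r = 0; r < nref; ++r) {
    IntegerVector pl(4 * L[r], 0), mx(4 * L[r], 0);
    const int *cc = cptr[r];
    for (int ind = 0; ind < n_ind; ++ind) {
      for (long t = 0; t < 4L * L[r]; ++t) {
        const int v = cc[t + 4L * L[r] * ind];
        pl[t] += v;
        if (v > mx[t]) mx[t] = v;
      }
    }
    pooled[r] = pl;
    maxind[r] = mx;
  }
  const size_t nid = idl.size();
  IntegerVector ir(nid), ip(nid), ii(nid), ic(nid);
  CharacterVector ira(nid), iaa(nid);
  size_t t = 0;
  for (auto &kv : idl) {
    ir[t] = std::get<0>(kv.first) + 1;
    ip[t] = std::get<1>(kv.first);
    ira[t] = std::get<2>(kv.first);
    iaa[t] = std::get<3>(kv.first);
    ii[t] = std::get<4>(kv.first) + 1;
    ic[t] = kv.second;
    ++t;
  }
  return List::create(
      _["counts"] = counts, _["pooled"] = pooled, _["maxind"] = maxind,
      _["indels"] = DataFrame::create(
          _["ref"] = ir, _["pos0"] = ip, _["ref_allele"] = ira,
          _["alt_allele"] = iaa, _["ind"] = ii, _["count"] = ic,
          _["stringsAsFactors"] = false),
      _["rejected"] = (double)rejected);
}
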