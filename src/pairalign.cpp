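// Pairwise alignment primitives shared by the clustering, consensus and
// read-mapping code: a banded affine-gap aligner (global in the query, free
// reference ends, optional trailing soft clip), banded and full unit-cost
// edit distances, and VCF-style indel left normalization.

#include "common.h"
using namespace Rcpp;

// Scoring: match +1, mismatch -1, gap of length g costs |open| + g * |extend|
static const int SC_MATCH = 1;
static const int SC_MISMATCH = -1;
static const int SC_GAP_OPEN = -2;
static const int SC_GAP_EXT = -1;

static const int NEG = INT_MIN / 4;

PairAln banded_affine(const std::string &q, const std::string &s, int diag,
                      int band, int clip_max) {
  PairAln res;
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0 || band < 1) return res;
  const int W = 2 * band;
  const size_t ncell = (size_t)(n + 1) * (W + 1);
  std::vector<int> H(ncell, NEG), D(ncell, NEG), I(ncell, NEG);
  std::vector<uint8_t> tbH(ncell, 0), tbD(ncell, 0), tbI(ncell, 0);
  // tbH: 0 = start, 1 = diagonal, 2 = from I, 3 = from D
  // tbI/tbD: 0 = open, 1 = extend

  auto base = [&](int i) { return i + diag - band; }; // j at idx 0 of row i
  auto idxof = [&](int i, int j) { return (size_t)i * (W + 1) + (j - base(i)); };
  auto jlo = [&](int i) { return std::max(0, base(i)); };
  auto jhi = [&](int i) { return std::min(m, base(i) + W); };

  for (int j = jlo(0); j <= jhi(0); ++j) H[idxof(0, j)] = 0; // free leading ref gap

  for (int i = 1; i <= n; ++i) {
    const int lo = jlo(i), hi = jhi(i);
    for (int j = lo; j <= hi; ++j) {
      const size_t at = idxof(i, j);
      // I: consume query base against a gap
      int off = j - base(i);
      if (off + 1 <= W && j >= jlo(i - 1) && j <= jhi(i - 1)) {
        const size_t up = idxof(i - 1, j);
        int open = (H[up] > NEG) ? H[up] + SC_GAP_OPEN + SC_GAP_EXT : NEG;
        int ext = (I[up] > NEG) ? I[up] + SC_GAP_EXT : NEG;
        if (open >= ext) { I[at] = open; tbI[at] = 0; }
        else             { I[at] = ext;  tbI[at] = 1; }
      }
      // D: consume reference base against a gap
      if (off - 1 >= 0 && j - 1 >= lo) {
        const size_t left = idxof(i, j - 1);
        int open = (H[left] > NEG) ? H[left] + SC_GAP_OPEN + SC_GAP_EXT : NEG;
        int ext = (D[left] > NEG) ? D[left] + SC_GAP_EXT : NEG;
        if (open >= ext) { D[at] = open; tbD[at] = 0; }
        else             { D[at] = ext;  tbD[at] = 1; }
      }
      // H: best of diagonal / I / D
      int best = NEG; uint8_t tb = 0;
      if (j >= 1 && j - 1 >= jlo(i - 1) && j - 1 <= jhi(i - 1)) {
        const size_t dg = idxof(i - 1, j - 1);
        if (H[dg] > NEG) {
          int sc = H[dg] + (q[i - 1] == s[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (sc > best) { best = sc; tb = 1; }
        }
      }
      if (I[at] > best) { best = I[at]; tb = 2; }
      if (D[at] > best) { best = D[at]; tb = 3; }
      if (best > NEG) { H[at] = best; tbH[at] = tb; }
    }
  }

  // Endpoint: full query consumed (any reference end, free), or reference
  // exhausted with <= clip_max trailing query bases soft-clipped.
  int bi = -1, bj = -1, bscore = NEG, bclip = 0;
  for (int j = jlo(n); j <= jhi(n); ++j) {
    int sc = H[idxof(n, j)];
    if (sc > bscore) { bscore = sc; bi = n; bj = j; bclip = 0; }
  }
  for (int c = 1; c <= clip_max; ++c) {
    int i = n - c;
    if (i < 1) break;
    if (m < jlo(i) || m > jhi(i)) continue;
    int sc = H[idxof(i, m)];
    if (sc > bscore) { bscore = sc; bi = i; bj = m; bclip = c; }
  }
  if (bscore <= NEG || bi < 0) return res;

  // Traceback
  std::vector<std::pair<char, int>> ops; // reversed
  int i = bi, j = bj, edit = 0;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  int state = 0; // 0 = H, 1 = I, 2 = D
  while (i > 0) {
    size_t at = idxof(i, j);
    if (state == 0) {
      uint8_t tb = tbH[at];
      if (tb == 0) break;
      if (tb == 1) {
        push('M');
        if (q[i - 1] != s[j - 1]) edit++;
        i--; j--;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      push('I'); edit++;
      uint8_t tb = tbI[at];
      i--;
      if (tb == 0) state = 0;
    } else {
      push('D'); edit++;
      uint8_t tb = tbD[at];
      j--;
      if (tb == 0) state = 0;
    }
  }
  res.ok = true;
  res.score = bscore;
  res.edit = edit;
  res.ref_start = j;
  res.clip = bclip;
  std::string cig;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    cig += std::to_string(ops[k].second);
    cig += ops[k].first;
  }
  if (bclip > 0) { cig += std::to_string(bclip); cig += 'S'; }
  res.cigar = cig;
  return res;
}

int banded_edit(const std::string &a, const std::string &b, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (band < 0) band = 0;
  if (std::abs(la - lb) > band) return band + 1;
  const int big = band + 1;
  const int W = 2 * band + 1;
  std::vector<int> prev(W, big), cur(W, big);
  for (int j = 0; j <= std::min(lb, band); ++j) prev[j + band] = j;
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), big);
    const int lo = std::max(0, i - band), hi = std::min(lb, i + band);
    for (int j = lo; j <= hi; ++j) {
      const int idx = j - (i - band);
      int best = big;
      if (idx + 1 < W && prev[idx + 1] + 1 < best) best = prev[idx + 1] + 1;
      if (idx - 1 >= 0 && j - 1 >= lo && cur[idx - 1] + 1 < best) best = cur[idx - 1] + 1;
      if (j >= 1) {
        int d = prev[idx] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (d < best) best = d;
      }
      cur[idx] = std::min(best, big);
    }
    std::swap(prev, cur);
  }
  const int idx = lb - (la - band);
  if (idx < 0 || idx >= W) return big;
  return std::min(prev[idx], big);
}

int edit_distance_full(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      d = std::min(d, prev[j] + 1);
      d = std::min(d, cur[j - 1] + 1);
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

void left_normalize(const std::string &refseq, int &anchor0, std::string &ref_a,
                    std::string &alt_a) {
  bool changed = true;
  while (changed) {
    changed = false;
    while (ref_a.size() > 1 && alt_a.size() > 1 && ref_a.back() == alt_a.back()) {
      ref_a.pop_back();
      alt_a.pop_back();
      changed = true;
    }
    if (!ref_a.empty() && !alt_a.empty() && ref_a.back() == alt_a.back() &&
        anchor0 > 0) {
      char prevc = refseq[anchor0 - 1];
      ref_a.insert(ref_a.begin(), prevc); ref_a.pop_back();
      alt_a.insert(alt_a.begin(), prevc); alt_a.pop_back();
      anchor0--;
      changed = true;
    }
  }
}

// [[Rcpp::export]]
List cpp_pair_align(std::string query, std::string ref, int diag, int band,
                    int clip_max) {
  PairAln a = banded_affine(query, ref, diag, band, clip_max);
  return List::create(_["ok"] = a.ok, _["score"] = a.score, _["edit"] = a.edit,
                      _["pos0"] = a.ref_start, _["clip"] = a.clip,
                      _["cigar"] = a.cigar);
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  return edit_distance_full(a, b);
}

// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  return banded_edit(a, b, band);
}

// [[Rcpp::export]]
List cpp_left_normalize(std::string refseq, int anchor0, std::string ref_allele,
                        std::string alt_allele) {
  left_normalize(refseq, anchor0, ref_allele, alt_allele);
  return List::create(_["anchor0"] = anchor0, _["ref"] = ref_allele,
                      _["alt"] = alt_allele);
}

// [[Rcpp::export]]
std::string cpp_consensus(std::string centroid, CharacterVector members,
                          IntegerVector counts, int band) {
  const int L = (int)centroid.size();
  std::vector<long> cnt(4 * (size_t)L, 0);
  for (int mi = 0; mi < members.size(); ++mi) {
    std::string mem = as<std::string>(members[mi]);
    long w = counts[mi];
    if (mem == centroid) {
      for (int j = 0; j < L; ++j) {
        int b = base_idx(centroid[j]);
        if (b >= 0) cnt[(size_t)j * 4 + b] += w;
      }
      continue;
    }
    int b2 = std::max(band, (int)std::abs((long)mem.size() - L) + 2);
    PairAln a = banded_affine(mem, centroid, 0, b2, b2);
    if (!a.ok) continue;
    int i = 0, j = a.ref_start;
    size_t p = 0;
    while (p < a.cigar.size()) {
      int len = 0;
      while (p < a.cigar.size() && isdigit(a.cigar[p]))
        len = len * 10 + (a.cigar[p++] - '0');
      char op = a.cigar[p++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int b = base_idx(mem[i + t]);
          if (b >= 0 && j + t < L) cnt[(size_t)(j + t) * 4 + b] += w;
        }
        i += len; j += len;
      } else if (op == 'I' || op == 'S') {
        i += len;
      } else if (op == 'D') {
        j += len;
      }
    }
  }
  std::string out(centroid);
  for (int j = 0; j < L; ++j) {
    int cb = base_idx(centroid[j]);
    int best = cb;
    long bc = (cb >= 0) ? cnt[(size_t)j * 4 + cb] : -1;
    for (int b = 0; b < 4; ++b) {
      if (cnt[(size_t)j * 4 + b] > bc) { bc = cnt[(size_t)j * 4 + b]; best = b; }
    }
    if (best >= 0) out[j] = BASES[best];
  }
  return out;
}
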