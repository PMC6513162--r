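// Read-simulation kernels. All randomness goes through R's RNG (unif_rand),
// so results are reproducible with set.seed() and a single integer seed.

#include "common.h"
using namespace Rcpp;

static inline int runif_int(int lo, int hi) {
  // uniform integer in [lo, hi]
  int r = lo + (int)(unif_rand() * (hi - lo + 1));
  if (r > hi) r = hi;
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_random_dna(IntegerVector lens) {
  const int n = lens.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const int L = lens[i];
    buf.assign(L, 'A');
    for (int j = 0; j < L; ++j) {
      int b = (int)(unif_rand() * 4.0);
      if (b > 3) b = 3;
      buf[j] = BASES[b];
    }
    out[i] = buf;
  }
  return out;
}

// Draw per-(fragment, individual) depths and emit error-laden reads.
// geno: n_frag x n_ind matrix of genotype codes (0 homRef, 1 het, 2 homAlt);
// hap_alt[f] is NA when fragment f carries no variant.
// [[Rcpp::export]]
List cpp_generate_reads(CharacterVector hap_ref, CharacterVector hap_alt,
                        IntegerMatrix geno, int depth_min, int depth_max,
                        double error_rate, int read_len, bool paired) {
  const int nf = hap_ref.size(), ni = geno.ncol();
  std::vector<std::string> seqs;
  std::vector<int> frag, ind, hap, mate;
  seqs.reserve((size_t)nf * ni * (depth_min + depth_max) / 2);
  long skipped = 0;
  std::string r1, r2;
  for (int f = 0; f < nf; ++f) {
    const std::string h1 = as<std::string>(hap_ref[f]);
    const bool has_alt = !CharacterVector::is_na(hap_alt[f]);
    const std::string h2 = has_alt ? as<std::string>(hap_alt[f]) : std::string();
    for (int i = 0; i < ni; ++i) {
      const int g = geno(f, i);
      const int d = runif_int(depth_min, depth_max);
      for (int t = 0; t < d; ++t) {
        int use_alt = 0;
        if (g == 2) use_alt = 1;
        else if (g == 1) use_alt = (unif_rand() < 0.5) ? 1 : 0;
        const std::string &h = use_alt ? h2 : h1;
        if ((int)h.size() < read_len) { skipped++; continue; }
        r1 = h.substr(0, read_len);
        for (int p = 0; p < read_len; ++p) {
          if (unif_rand() < error_rate) {
            int b = base_idx(r1[p]);
            int nb = (int)(unif_rand() * 3.0);
            if (nb > 2) nb = 2;
            if (nb >= b) nb++;
            r1[p] = BASES[nb];
          }
        }
        seqs.push_back(r1);
        frag.push_back(f + 1);
        ind.push_back(i + 1);
        hap.push_back(use_alt + 1);
        mate.push_back(paired ? 1 : 0);
        if (paired) {
          r2 = revcomp_str(h.substr(h.size() - read_len, read_len));
          for (int p = 0; p < read_len; ++p) {
            if (unif_rand() < error_rate) {
              int b = base_idx(r2[p]);
              int nb = (int)(unif_rand() * 3.0);
              if (nb > 2) nb = 2;
              if (nb >= b) nb++;
              r2[p] = BASES[nb];
            }
          }
          seqs.push_back(r2);
          frag.push_back(f + 1);
          ind.push_back(i + 1);
          hap.push_back(use_alt + 1);
          mate.push_back(2);
        }
      }
    }
  }
  return List::create(_["sequence"] = wrap(seqs), _["frag"] = wrap(frag),
                      _["ind"] = wrap(ind), _["hap"] = wrap(hap),
                      _["mate"] = wrap(mate), _["skipped"] = (double)skipped);
}
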