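# Independent reference implementations used as oracles, plus small fixture
# builders. Oracles deliberately avoid the package's C++ code paths:
# utils::adist for edit distance, plain-R DP for alignment scores, and a
# literal translation of the greedy clustering rule.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutate_seq <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

oracle_identity <- function(a, b) {
  1 - drop(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

# Literal greedy clustering: first centroid (in founding order) at identity
# >= threshold wins, else found a new cluster if the abundance floor allows.
oracle_greedy <- function(seqs, counts, threshold, min_count = 1L) {
  ord <- order(-nchar(seqs), -counts, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord]
  cl <- rep(NA_integer_, length(seqs))
  cent <- integer(0)
  for (i in seq_along(seqs)) {
    hit <- NA_integer_
    for (ci in seq_along(cent)) {
      if (oracle_identity(seqs[i], seqs[cent[ci]]) >= threshold) {
        hit <- ci
        break
      }
    }
    if (!is.na(hit)) cl[i] <- hit
    else if (counts[i] >= min_count) {
      cent <- c(cent, i)
      cl[i] <- length(cent)
    }
  }
  list(sequence = seqs, count = counts, cluster = cl)
}

# Unbanded glocal affine-gap DP (score only): global in the query, free
# leading/trailing reference gaps, no soft clipping.
r_gotoh_score <- function(q, s, ma = 1, mm = -1, go = -2, ge = -1) {
  n <- nchar(q)
  m <- nchar(s)
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  H[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      I[i, j] <- max(H[i - 1, j] + go + ge, I[i - 1, j] + ge)
      best <- I[i, j]
      if (j > 1) {
        D[i, j] <- max(H[i, j - 1] + go + ge, D[i, j - 1] + ge)
        diagv <- H[i - 1, j - 1] + if (qc[i - 1] == sc[j - 1]) ma else mm
        best <- max(best, D[i, j], diagv)
      }
      H[i, j] <- best
    }
  }
  max(H[n + 1, ])
}

# Small simulation used by several suites.
tiny_sim <- function(seed = 7, n_fragments = 60, n_snps = 15, n_indels = 6,
                     n_individuals = 6, error_rate = 0.011, ...) {
  simulate_gbs(sim_config(n_fragments = n_fragments, n_snps = n_snps,
                          n_indels = n_indels, n_individuals = n_individuals,
                          error_rate = error_rate, seed = seed, ...))
}

run_small_pipeline <- function(sim, min_count = 2L, ...) {
  mr <- build_mock_reference(sim$reads, min_count = min_count, ...)
  idx <- build_kmer_index(mr)
  aln <- align_reads(sim$reads, idx)
  pile <- make_pileup(aln, sim$reads, mr)
  calls <- call_population(pile)
  list(mr = mr, aln = aln, pile = pile, calls = calls)
}
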