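# Read mapping against the Mock Reference: k-mer index, seeded banded
# alignment, and pileup accumulation.

#' Build a k-mer index over reference sequences
#'
#' Every k-mer of every sequence is indexed with its (sequence, offset)
#' occurrence list. Sequences shorter than `k` are skipped with a warning.
#'
#' @param x a `mock_reference`, or a (optionally named) character vector of
#'   sequences.
#' @param k seed length in bp (1-31).
#' @return object of class `kmer_index` (opaque pointer plus `ids`, `k`).
#' @export
build_kmer_index <- function(x, k = 20L) {
  if (inherits(x, "mock_reference")) {
    seqs <- x$centroids$sequence
    ids <- x$centroids$centroid_id
  } else {
    seqs <- as.character(x)
    ids <- names(x) %||% fmt_ids("seq", length(seqs))
  }
  ptr <- cpp_build_index(seqs, as.integer(k))
  st <- cpp_index_stats(ptr)
  if (st$n_skipped > 0)
    warning(st$n_skipped, " sequence(s) shorter than k were not indexed",
            call. = FALSE)
  structure(list(ptr = ptr, k = as.integer(k), ids = ids, seqs = seqs,
                 n_positions = st$n_positions),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- cpp_index_stats(x$ptr)
  cat(sprintf("k-mer index: k=%d, %d sequences, %s positions, %s distinct k-mers\n",
              st$k, st$n_seqs, format(st$n_positions, big.mark = ","),
              format(st$n_kmers, big.mark = ",")))
  invisible(x)
}

#' k-mer index summary statistics
#'
#' @param index a [build_kmer_index()] object.
#' @return list with `k`, `n_seqs`, `n_positions`, `n_kmers`, `n_skipped`.
#' @export
kmer_index_stats <- function(index) {
  cpp_index_stats(index$ptr)
}

#' Banded pairwise alignment
#'
#' The scoring engine behind [align_reads()] and [cluster_consensus()],
#' exposed for inspection: global in the query with free reference ends,
#' affine gaps (match +1, mismatch -1, gap open -2, gap extend -1), band of
#' half-width `band` around `diag`, optional trailing soft clip of up to
#' `clip_max` query bases once the reference is exhausted. A `band` at
#' least as large as `max(nchar(query), nchar(ref))` makes the DP unbanded.
#'
#' @param query,ref DNA strings.
#' @param diag expected diagonal (reference start minus query start).
#' @param band band half-width in bp.
#' @param clip_max maximum trailing soft clip.
#' @return list with `ok`, `score`, `edit` (mismatches + gap bases),
#'   `pos0`, `clip`, `cigar`.
#' @export
banded_align <- function(query, ref, diag = 0L, band = 12L, clip_max = band) {
  cpp_pair_align(query, ref, as.integer(diag), as.integer(band),
                 as.integer(clip_max))
}

#' Map reads to the Mock Reference
#'
#' Candidate centroids are gathered from shared seed k-mers of the read and
#' its reverse complement; each candidate is scored by a banded
#' global-in-read alignment (match +1, mismatch -1, gap open -2, gap extend
#' -1) around the best-voted diagonal. A read is reported mapped when its
#' best alignment has edit distance (mismatches plus gap bases) at most
#' `max_mismatch_frac` times the read length; reads whose equally-best
#' alignment lands on more than one centroid are reported unmapped
#' (unique-mapping policy). Ties on one centroid are broken by lower edit
#' distance, then more seed hits.
#'
#' @param reads `data.table` with `read_id`, `individual_id`, `sequence`
#'   columns (e.g. `sim$reads`), or a character vector of sequences.
#' @param index a [build_kmer_index()] object.
#' @param max_mismatch_frac maximum edit distance as a fraction of read
#'   length.
#' @param band alignment band width (must exceed the longest expected
#'   indel).
#' @param fast_max candidates whose best seed diagonal explains the read
#'   with at most this many mismatches skip the DP and are reported as
#'   all-M alignments.
#' @param stride seed sampling stride along the read.
#' @param max_cand maximum candidate centroids evaluated per read.
#' @return `data.table` with columns `read_id`, `individual_id`,
#'   `centroid_id` (`NA` when unmapped), `pos0` (0-based leftmost), `cigar`
#'   (over M/I/D/S), `strand`, `edit`, in input read order.
#' @export
align_reads <- function(reads, index, max_mismatch_frac = 0.1, band = 12L,
                        fast_max = 4L, stride = 7L, max_cand = 8L) {
  if (!inherits(index, "kmer_index")) stop("index must be a kmer_index")
  if (is.character(reads))
    reads <- data.table(read_id = fmt_ids("read", length(reads)),
                        individual_id = "ind01", sequence = reads)
  res <- cpp_align_reads(index$ptr, reads$sequence, max_mismatch_frac,
                         as.integer(band), as.integer(fast_max),
                         as.integer(stride), as.integer(max_cand))
  data.table(read_id = reads$read_id, individual_id = reads$individual_id,
             centroid_id = index$ids[res$ref], pos0 = res$pos0,
             cigar = res$cigar, strand = res$strand, edit = res$edit)
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param sequence read sequence.
#' @inheritParams align_reads
#' @param ... passed to [align_reads()].
#' @return one-row `data.table` as in [align_reads()].
#' @export
align_read <- function(sequence, index, ...) {
  align_reads(data.table(read_id = "read1", individual_id = "ind01",
                         sequence = sequence), index, ...)
}

#' Accumulate per-individual pileups
#'
#' M segments contribute per-base depth; I/D segments contribute
#' left-normalized indel-allele counts anchored on the base preceding the
#' event (VCF convention). Alignments overrunning their centroid are
#' rejected with a warning.
#'
#' @param alignments output of [align_reads()] (row order must match
#'   `reads`).
#' @param reads the read table that was aligned.
#' @param mr the `mock_reference` the index was built from.
#' @return object of class `gbs_pileup`: `centroid_id`, `sequences`,
#'   `counts` (per centroid an integer array `dim = c(4, L, n_ind)` over
#'   bases A/C/G/T), `pooled` (4 x L, summed over individuals), `maxind`
#'   (4 x L, per-base maximum over individuals), `indels` (`data.table`:
#'   `centroid_id`, `pos0`, `ref_allele`, `alt_allele`, `individual_id`,
#'   `count`), `individuals`.
#' @export
make_pileup <- function(alignments, reads, mr) {
  if (nrow(alignments) != nrow(reads))
    stop("alignments and reads must have matching rows", call. = FALSE)
  centroids <- if (inherits(mr, "mock_reference")) mr$centroids else mr
  inds <- sort(unique(reads$individual_id))
  ref1 <- match(alignments$centroid_id, centroids$centroid_id)
  ind1 <- match(alignments$individual_id, inds)
  res <- cpp_make_pileup(centroids$sequence, reads$sequence, ref1,
                         alignments$pos0, alignments$cigar,
                         alignments$strand, ind1, length(inds))
  if (res$rejected > 0)
    warning(res$rejected, " alignment record(s) rejected (centroid overrun)",
            call. = FALSE)
  L <- nchar(centroids$sequence)
  counts <- res$counts
  pooled <- res$pooled
  maxind <- res$maxind
  for (i in seq_along(counts)) {
    dim(counts[[i]]) <- c(4L, L[i], length(inds))
    dim(pooled[[i]]) <- c(4L, L[i])
    dim(maxind[[i]]) <- c(4L, L[i])
  }
  idl <- as.data.table(res$indels)
  idl <- data.table(centroid_id = centroids$centroid_id[idl$ref],
                    pos0 = idl$pos0, ref_allele = as.character(idl$ref_allele),
                    alt_allele = as.character(idl$alt_allele),
                    individual_id = inds[idl$ind], count = idl$count)
  structure(list(centroid_id = centroids$centroid_id,
                 sequences = centroids$sequence, counts = counts,
                 pooled = pooled, maxind = maxind, indels = idl,
                 individuals = inds),
            class = "gbs_pileup")
}

#' @export
print.gbs_pileup <- function(x, ...) {
  cat(sprintf("pileup over %d centroids x %d individuals (%d indel allele records)\n",
              length(x$centroid_id), length(x$individuals), nrow(x$indels)))
  invisible(x)
}
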