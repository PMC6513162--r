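# Mock Reference construction: dereplication, greedy centroid clustering by
# global sequence identity, and per-cluster consensus building.

#' Collapse reads to unique sequences
#'
#' Exact-match dereplication. Counts are conserved: the sum of `count`
#' equals the number of input reads.
#'
#' @param reads character vector of read sequences, or a `data.table` with a
#'   `sequence` column.
#' @return `data.table` with columns `sequence`, `count`, sorted by
#'   decreasing length, then decreasing count, then sequence — the
#'   processing order used by [greedy_cluster()].
#' @export
dereplicate <- function(reads) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (length(reads) == 0)
    return(data.table(sequence = character(0), count = integer(0)))
  dt <- data.table(sequence = reads)[, .(count = .N), by = sequence]
  dt[order(-nchar(sequence), -count, sequence)]
}

#' Global pairwise sequence identity
#'
#' `1 - d / max(|a|, |b|)` where `d` is the unit-cost (Levenshtein) edit
#' distance between the full sequences.
#'
#' @param a,b non-empty DNA strings.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b))
    stop("pairwise_identity requires non-empty sequences", call. = FALSE)
  1 - cpp_edit_distance(a, b) / max(nchar(a), nchar(b))
}

#' Greedy centroid clustering
#'
#' Processes unique sequences in decreasing (length, count, lexicographic)
#' order. Each sequence joins the first existing centroid whose identity
#' (see [pairwise_identity()]) is at least `identity_threshold`; otherwise
#' it founds a new cluster, provided its count reaches `min_count`
#' (sequences below the floor that match no centroid are left unassigned —
#' an error-suppression device for noisy reads).
#'
#' @param uniques output of [dereplicate()] (a character vector is
#'   dereplicated first).
#' @param identity_threshold fraction in (0, 1].
#' @param min_count abundance floor for founding a cluster.
#' @return list of class `gbs_clusters`: `members` (`data.table`:
#'   `sequence`, `count`, `cluster`, `identity`; `cluster` is `NA` for
#'   unassigned sequences) and `centroids` (`data.table`: `cluster`,
#'   `sequence`, `n_members`, `n_reads`).
#' @export
greedy_cluster <- function(uniques, identity_threshold = 0.93,
                           min_count = 1L) {
  if (!is.data.frame(uniques)) uniques <- dereplicate(uniques)
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  uniques <- uniques[order(-nchar(sequence), -count, sequence)]
  res <- cpp_greedy_cluster(uniques$sequence, as.integer(uniques$count),
                            identity_threshold, as.integer(min_count))
  members <- data.table(sequence = uniques$sequence, count = uniques$count,
                        cluster = res$cluster, identity = res$identity)
  cent <- members[!is.na(cluster),
                  .(n_members = .N, n_reads = sum(count)), by = cluster]
  cent[, sequence := uniques$sequence[res$centroid_idx[cluster]]]
  setorder(cent, cluster)
  setcolorder(cent, c("cluster", "sequence", "n_members", "n_reads"))
  structure(list(members = members[], centroids = cent[]),
            class = "gbs_clusters")
}

#' @export
print.gbs_clusters <- function(x, ...) {
  cat(sprintf("%d clusters over %d unique sequences (%d unassigned)\n",
              nrow(x$centroids), nrow(x$members), sum(is.na(x$members$cluster))))
  invisible(x)
}

#' Consensus sequence of a cluster
#'
#' Members are globally aligned to the centroid (banded, affine gaps); each
#' centroid column emits the count-weighted majority base, with ties
#' resolved in favor of the centroid base. Member insertions relative to the
#' centroid are ignored, so the consensus length equals the centroid length.
#'
#' @param centroid centroid sequence.
#' @param members member sequences (should include the centroid itself).
#' @param counts read counts per member.
#' @param band alignment band width.
#' @return consensus DNA string.
#' @export
cluster_consensus <- function(centroid, members, counts = rep(1L, length(members)),
                              band = 12L) {
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  cpp_consensus(centroid, members, as.integer(counts), as.integer(band))
}

#' Build the Mock Reference
#'
#' Pools the reads of the selected individuals, dereplicates, clusters
#' greedily at `identity_threshold`, and emits one consensus sequence per
#' cluster. The default selection is the single most read-abundant
#' individual — the recommended data-usage practice for mock-reference
#' assembly; using more individuals generally does not improve and can
#' degrade downstream accuracy.
#'
#' @param reads `data.table` with `individual_id` and `sequence` columns
#'   (e.g. `sim$reads`).
#' @param individuals `"best"` (most reads), an integer N (top-N by read
#'   count), or a character vector of individual ids.
#' @param identity_threshold clustering identity threshold.
#' @param min_count abundance floor for founding clusters; unique sequences
#'   seen fewer times can still join clusters but never found one, which
#'   suppresses error-only centroids.
#' @param band consensus alignment band.
#' @return object of class `mock_reference`: list with `centroids`
#'   (`data.table`: `centroid_id`, `sequence`, `size` = supporting reads),
#'   `clusters` (the [greedy_cluster()] result) and `selection` (individual
#'   ids used).
#' @export
build_mock_reference <- function(reads, individuals = "best",
                                 identity_threshold = 0.93, min_count = 2L,
                                 band = 12L) {
  counts <- data.table(individual_id = reads$individual_id)[
    , .(n = .N), by = individual_id][order(-n, individual_id)]
  sel <-
    if (identical(individuals, "best")) counts$individual_id[1]
    else if (is.numeric(individuals)) head(counts$individual_id,
                                           as.integer(individuals))
    else as.character(individuals)
  if (length(sel) == 0 || anyNA(sel))
    stop("empty individual selection for mock reference", call. = FALSE)
  missing_ids <- setdiff(sel, counts$individual_id)
  if (length(missing_ids))
    stop("unknown individual id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  pool <- reads$sequence[reads$individual_id %in% sel]
  uniq <- dereplicate(pool)
  cl <- greedy_cluster(uniq, identity_threshold, min_count = min_count)
  cent <- cl$centroids
  cons <- character(nrow(cent))
  for (i in seq_len(nrow(cent))) {
    mem <- cl$members[cluster == cent$cluster[i]]
    cons[i] <- cpp_consensus(cent$sequence[i], mem$sequence,
                             as.integer(mem$count), as.integer(band))
  }
  centroids <- data.table(centroid_id = fmt_ids("MR", nrow(cent)),
                          sequence = cons, size = cent$n_reads)
  structure(list(centroids = centroids, clusters = cl, selection = sel),
            class = "mock_reference")
}

#' @export
print.mock_reference <- function(x, ...) {
  cat(sprintf("Mock Reference: %d centroids (from %s), %s supporting reads\n",
              nrow(x$centroids), paste(x$selection, collapse = ", "),
              format(sum(x$centroids$size), big.mark = ",")))
  invisible(x)
}

#' Write the Mock Reference as FASTA
#'
#' Headers carry the centroid id and cluster size.
#'
#' @param mr a `mock_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mock_reference <- function(mr, path) {
  write_fasta(setNames(mr$centroids$sequence,
                       sprintf("%s size=%d", mr$centroids$centroid_id,
                               mr$centroids$size)),
              path)
}
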