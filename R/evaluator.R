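# Truth-based validation: anchor mock-reference centroids to their source
# fragments, match calls against induced variants, and compute Type I /
# Type II error and overall accuracy.

#' Anchor centroids to source fragments
#'
#' Each centroid is aligned against the simulated fragments with the k-mer
#' seeded banded aligner; a centroid maps to at most one fragment (the
#' unique best alignment) and must reach `min_identity`, computed as
#' `1 - edits / centroid length` over the aligned window. Unmatched
#' centroids are recorded.
#'
#' @param mr a `mock_reference`.
#' @param fragments the simulation fragment table.
#' @param min_identity minimum alignment identity.
#' @param k,band aligner parameters.
#' @return `data.table`: `centroid_id`, `fragment_id` (`NA` when
#'   unmatched), `pos0`, `cigar`, `strand`, `identity`.
#' @export
map_centroids <- function(mr, fragments, min_identity = 0.9, k = 20L,
                          band = 12L) {
  centroids <- if (inherits(mr, "mock_reference")) mr$centroids else mr
  idx <- build_kmer_index(setNames(fragments$sequence, fragments$fragment_id),
                          k = k)
  aln <- align_reads(
    data.table(read_id = centroids$centroid_id, individual_id = "mr",
               sequence = centroids$sequence),
    idx, max_mismatch_frac = 1 - min_identity, band = band)
  data.table(centroid_id = centroids$centroid_id,
             fragment_id = aln$centroid_id, pos0 = aln$pos0,
             cigar = aln$cigar, strand = aln$strand,
             identity = 1 - aln$edit / nchar(centroids$sequence))
}

#' Match calls against truth variants
#'
#' Each call is projected onto its centroid's source fragment through the
#' [map_centroids()] alignment. A call validates when a truth record exists
#' on that fragment at the projected coordinate (exact for SNPs, within
#' `indel_slack` bp for indels, both sides left-normalized) and the
#' unordered allele pair matches the truth pair in content — the comparison
#' is orientation-adjusted, because a centroid that itself carries the alt
#' allele yields calls whose REF/ALT are swapped relative to the truth
#' table. Matching is one-to-one: each truth record validates at most one
#' call (greedy, ordered by projected position).
#'
#' @param calls a `gbs_calls` object (or its `calls` table).
#' @param truth the truth variant table (`fragment_id`, `offset0`,
#'   `ref_allele`, `alt_allele`, `vtype`).
#' @param cmap output of [map_centroids()].
#' @param indel_slack positional slack for indels in bp.
#' @return the calls table plus `fragment_id`, `proj_offset0`, `validated`
#'   and `truth_idx` (row of the matched truth record, `NA` otherwise).
#' @export
match_variants <- function(calls, truth, cmap, indel_slack = 2L) {
  cc <- if (inherits(calls, "gbs_calls")) copy(calls$calls) else copy(calls)
  cm <- cmap[match(cc$centroid_id, cmap$centroid_id)]
  cc[, fragment_id := cm$fragment_id]
  cc[, proj_offset0 := NA_integer_]
  ok <- !is.na(cc$fragment_id)
  for (i in which(ok)) {
    cc$proj_offset0[i] <- project_through_cigar(cm$cigar[i], cm$pos0[i],
                                                cc$pos1[i] - 1L)
  }
  cc[, `:=`(validated = FALSE, truth_idx = NA_integer_)]
  if (nrow(cc) == 0 || nrow(truth) == 0) return(cc[])
  truth_used <- rep(FALSE, nrow(truth))
  setorder(cc, fragment_id, proj_offset0, pos1, na.last = TRUE)
  tf <- split(seq_len(nrow(truth)), truth$fragment_id)
  for (i in seq_len(nrow(cc))) {
    f <- cc$fragment_id[i]
    po <- cc$proj_offset0[i]
    if (is.na(f) || is.na(po)) next
    cand <- tf[[f]]
    if (is.null(cand)) next
    pair_call <- sort(c(cc$ref_allele[i], cc$alt_allele[i]))
    is_indel <- cc$vtype[i] != "SNP"
    for (t in cand) {
      if (truth_used[t]) next
      slack <- if (is_indel || truth$vtype[t] != "SNP") indel_slack else 0L
      if (abs(truth$offset0[t] - po) > slack) next
      pair_truth <- sort(c(truth$ref_allele[t], truth$alt_allele[t]))
      if (length(pair_call) == length(pair_truth) &&
          all(pair_call == pair_truth)) {
        cc$validated[i] <- TRUE
        cc$truth_idx[i] <- t
        truth_used[t] <- TRUE
        break
      }
    }
  }
  cc[]
}

#' Evaluation metrics (Type I, Type II, accuracy)
#'
#' `type1 = 100 (n_called - n_validated) / n_called` — the percentage of
#' called variants that could not be validated (false positives; 0 when
#' nothing was called). `type2 = 100 (n_simulated - n_validated) /
#' n_simulated` — the percentage of true simulated variants not detected.
#' `accuracy = 100 n_validated / (n_simulated + (n_called - n_validated))`.
#' Percentages are displayed at one decimal; full precision is retained in
#' the object.
#'
#' @param n_simulated,n_called,n_validated variant counts.
#' @return object of class `evaluation_report` with the three counts and
#'   three percentages.
#' @export
compute_metrics <- function(n_simulated, n_called, n_validated) {
  if (n_validated > n_called)
    stop("n_validated exceeds n_called", call. = FALSE)
  if (n_simulated > 0 && n_validated > n_simulated)
    stop("n_validated exceeds n_simulated", call. = FALSE)
  type1 <- if (n_called > 0) 100 * (n_called - n_validated) / n_called else 0
  type2 <- if (n_simulated > 0)
    100 * (n_simulated - n_validated) / n_simulated else 0
  accuracy <- if (n_simulated + n_called - n_validated > 0)
    100 * n_validated / (n_simulated + (n_called - n_validated)) else 0
  structure(list(n_simulated = n_simulated, n_called = n_called,
                 n_validated = n_validated, type1 = type1, type2 = type2,
                 accuracy = accuracy),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("simulated %d | called %d | validated %d\n",
              x$n_simulated, x$n_called, x$n_validated))
  cat(sprintf("Type I %.1f%% | Type II %.1f%% | accuracy %.1f%%\n",
              x$type1, x$type2, x$accuracy))
  invisible(x)
}

#' Evaluate a call set against simulation truth
#'
#' Convenience wrapper: [map_centroids()], [match_variants()],
#' [compute_metrics()], plus a genotype-concordance diagnostic when truth
#' genotypes are supplied (orientation-harmonized: calls whose REF equals
#' the truth ALT have their genotypes flipped before comparison).
#'
#' @param calls a `gbs_calls` object.
#' @param truth truth variant table.
#' @param mr the `mock_reference`.
#' @param fragments simulation fragment table.
#' @param genotypes optional truth genotype table (`individual_id`,
#'   `fragment_id`, `genotype`).
#' @param indel_slack positional slack for indels.
#' @return list with `report` (`evaluation_report`), `per_call`
#'   (validation table), `centroid_map`, and `concordance` (fraction of
#'   genotypes agreeing with truth at validated calls; `NA` without truth
#'   genotypes).
#' @export
evaluate_calls <- function(calls, truth, mr, fragments, genotypes = NULL,
                           indel_slack = 2L) {
  cmap <- map_centroids(mr, fragments)
  per_call <- match_variants(calls, truth, cmap, indel_slack)
  report <- compute_metrics(nrow(truth), nrow(per_call),
                            sum(per_call$validated))
  concordance <- NA_real_
  if (!is.null(genotypes) && nrow(per_call) > 0) {
    val <- per_call[validated == TRUE]
    if (nrow(val) > 0) {
      g <- calls$genotypes[variant_id %in% val$variant_id]
      g <- merge(g, val[, .(variant_id, truth_idx, fragment_id,
                            call_ref = ref_allele)],
                 by = "variant_id")
      g[, truth_ref := truth$ref_allele[truth_idx]]
      flip <- g$call_ref != g$truth_ref
      g[flip & gt == "homRef", gt := "homAlt_f"]
      g[flip & gt == "homAlt", gt := "homRef"]
      g[gt == "homAlt_f", gt := "homAlt"]
      g <- merge(g, genotypes, by = c("individual_id", "fragment_id"))
      cmp <- g[gt != "missing"]
      concordance <- if (nrow(cmp)) mean(cmp$gt == cmp$genotype) else NA_real_
    }
  }
  list(report = report, per_call = per_call, centroid_map = cmap,
       concordance = concordance)
}

#' Write the evaluation report
#'
#' @param ev output of [evaluate_calls()] (or an `evaluation_report`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  rep_ <- if (inherits(ev, "evaluation_report")) ev else ev$report
  dt <- data.table(n_simulated = rep_$n_simulated, n_called = rep_$n_called,
                   n_validated = rep_$n_validated,
                   type1_pct = round(rep_$type1, 1),
                   type2_pct = round(rep_$type2, 1),
                   accuracy_pct = round(rep_$accuracy, 1))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
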