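# k-mer index, seeded banded alignment (with unbanded DP oracle), and
# pileup accumulation.

test_that("k-mer index counts L - k + 1 positions per sequence", {
  idx <- build_kmer_index("ACGTACGT", k = 4)
  expect_equal(kmer_index_stats(idx)$n_positions, 5)
  idx2 <- build_kmer_index("ACGTACGT", k = 8)
  expect_equal(kmer_index_stats(idx2)$n_positions, 1)
  # identical sequences are indexed at both occurrences
  idx3 <- build_kmer_index(c(a = "ACGTACGTACGTACGTACGTACGT",
                             b = "ACGTACGTACGTACGTACGTACGT"), k = 20)
  expect_equal(kmer_index_stats(idx3)$n_positions, 10)
  expect_warning(build_kmer_index(c("ACGTACGTACGTACGTACGTACGT", "ACG"), k = 20),
                 "shorter than k")
})

test_that("exact prefix reads map at position 0 with an all-M CIGAR", {
  set.seed(101)
  refs <- random_dna(5, 200)
  idx <- build_kmer_index(setNames(refs, paste0("MR", 1:5)))
  rd <- substr(refs[3], 1, 150)
  a <- align_read(rd, idx)
  expect_identical(a$centroid_id, "MR3")
  expect_equal(a$pos0, 0)
  expect_identical(a$cigar, "150M")
  expect_equal(a$edit, 0)
  expect_identical(a$strand, "+")
})

test_that("substituted and indel-bearing reads map with the right edit distance", {
  set.seed(103)
  refs <- random_dna(4, 220)
  idx <- build_kmer_index(setNames(refs, paste0("MR", 1:4)))
  rd <- mutate_seq(substr(refs[2], 1, 150), 2)
  a <- align_read(rd, idx, max_mismatch_frac = 0.1)
  expect_identical(a$centroid_id, "MR2")
  expect_equal(a$edit, 2)
  # 4 bp deletion read: edit = 4, D in the CIGAR
  rd_del <- substr(paste0(substr(refs[2], 1, 60), substr(refs[2], 65, 220)),
                   1, 150)
  ad <- align_read(rd_del, idx)
  expect_identical(ad$centroid_id, "MR2")
  expect_equal(ad$edit, 4)
  expect_match(ad$cigar, "4D")
  # read beyond the mismatch budget is unmapped
  rd_bad <- mutate_seq(substr(refs[2], 1, 150), 30)
  expect_true(is.na(align_read(rd_bad, idx, max_mismatch_frac = 0.1)$centroid_id))
})

test_that("reads matching two centroids equally are unmapped (unique-mapping)", {
  set.seed(107)
  s <- random_dna(1, 200)
  idx <- build_kmer_index(setNames(c(s, s, random_dna(1, 200)),
                                   c("MR1", "MR2", "MR3")))
  a <- align_read(substr(s, 1, 150), idx)
  expect_true(is.na(a$centroid_id))
})

test_that("strand closure: the reverse complement maps to the same place on '-'", {
  set.seed(109)
  refs <- random_dna(3, 210)
  idx <- build_kmer_index(setNames(refs, paste0("MR", 1:3)))
  rd <- mutate_seq(substr(refs[1], 11, 160), 1)
  fwd <- align_read(rd, idx)
  rev <- align_read(gbsnp:::revcomp(rd), idx)
  expect_identical(rev$centroid_id, fwd$centroid_id)
  expect_equal(rev$pos0, fwd$pos0)
  expect_equal(rev$edit, fwd$edit)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "-")
})

test_that("banded alignment score equals the unbanded DP when edits fit the band", {
  set.seed(113)
  for (i in 1:30) {
    ref <- random_dna(1, sample(80:140, 1))
    q <- substr(ref, 1, 70)
    nmut <- sample(0:4, 1)
    if (nmut > 0) q <- mutate_seq(q, nmut)
    if (i %% 3 == 0) { # add a small internal deletion
      cut <- sample(20:40, 1)
      q <- paste0(substr(q, 1, cut), substr(q, cut + 3, nchar(q)))
    }
    banded <- banded_align(q, ref, 0L, 12L, 0L)
    expect_true(banded$ok)
    expect_equal(banded$score, r_gotoh_score(q, ref),
                 label = paste("pair", i))
  }
})

test_that("pileup conserves depth and counts indels at the left-anchored column", {
  set.seed(127)
  ref <- random_dna(1, 150)
  mrdt <- data.table::data.table(centroid_id = "MR1", sequence = ref)
  reads <- data.table::data.table(
    read_id = c("r1", "r2"), individual_id = c("ind01", "ind02"),
    sequence = c(ref, paste0(substr(ref, 1, 10), substr(ref, 13, 150))))
  aln <- data.table::data.table(
    read_id = reads$read_id, individual_id = reads$individual_id,
    centroid_id = "MR1", pos0 = 0L, cigar = c("150M", "10M2D138M"),
    strand = "+", edit = c(0L, 2L))
  pile <- make_pileup(aln, reads, mrdt)
  # deletion allele recorded once, anchored at column 9 (0-based)
  expect_equal(nrow(pile$indels), 1)
  del <- pile$indels[1]
  expect_identical(del$individual_id, "ind02")
  expect_equal(nchar(del$ref_allele) - nchar(del$alt_allele), 2)
  # possibly shifted left of the naive anchor by normalization, never right
  expect_lte(del$pos0, 9)
  expect_equal(del$count, 1)
  # per-individual depth: read 1 covers all 150 columns, read 2 all but the
  # two deleted columns
  depth_per_ind <- apply(pile$counts[[1]], 3, sum)
  expect_equal(unname(depth_per_ind), c(150L, 148L))
  # per-column totals at an unaffected column
  expect_equal(sum(pile$counts[[1]][, 5, ]), 2)
})

test_that("pileup depth equals summed aligned M-length per individual", {
  sim <- tiny_sim(seed = 131)
  ps <- run_small_pipeline(sim)
  aln <- ps$aln[!is.na(centroid_id)]
  mlen <- sapply(aln$cigar, function(cg) {
    ops <- gbsnp:::parse_cigar(cg)
    sum(ops[ops$op == "M"]$len)
  })
  expected <- tapply(mlen, aln$individual_id, sum)
  observed <- sapply(seq_along(ps$pile$individuals), function(i)
    sum(sapply(ps$pile$counts, function(a) sum(a[, , i]))))
  names(observed) <- ps$pile$individuals
  expect_equal(unname(observed[names(expected)]), as.vector(expected))
})

test_that("alignment output is independent of read partitioning", {
  sim <- tiny_sim(seed = 137, n_fragments = 30, n_snps = 8, n_indels = 3,
                  n_individuals = 3)
  mr <- build_mock_reference(sim$reads)
  idx <- build_kmer_index(mr)
  whole <- align_reads(sim$reads, idx)
  parts <- lapply(split(seq_len(nrow(sim$reads)),
                        rep(1:4, length.out = nrow(sim$reads))),
                  function(ix) align_reads(sim$reads[ix], idx))
  merged <- data.table::rbindlist(parts)[order(match(read_id, whole$read_id))]
  expect_equal(merged$centroid_id, whole$centroid_id)
  expect_equal(merged$pos0, whole$pos0)
  expect_equal(merged$cigar, whole$cigar)
})
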