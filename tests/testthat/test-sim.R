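# Simulator: configuration validation, fragment space, variant induction,
# Hardy-Weinberg genotype sampling, and read generation.

test_that("invalid configurations are rejected with the violated constraint", {
  expect_error(sim_config(n_fragments = 5, n_snps = 6, n_indels = 0),
               "one variant per fragment")
  expect_error(sim_config(fragment_length_range = c(100, 400)),
               "read_length")
  expect_error(sim_config(depth_range = c(0, 5)), "depth_range")
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("make_fragments yields distinct fragments of valid length, deterministically", {
  cfg <- sim_config(n_fragments = 500, n_snps = 0, n_indels = 0, seed = 11)
  set.seed(123)
  fr <- make_fragments(cfg)
  expect_equal(nrow(fr), 500)
  expect_false(anyDuplicated(fr$sequence) > 0)
  lens <- nchar(fr$sequence)
  expect_true(all(lens >= 240 & lens <= 400))
  set.seed(123)
  fr2 <- make_fragments(cfg)
  expect_identical(fr, fr2)
  # single fragment edge case
  cfg1 <- sim_config(n_fragments = 1, n_snps = 0, n_indels = 0)
  expect_equal(nrow(make_fragments(cfg1)), 1)
})

test_that("induce_variants honors counts, uniqueness and placement", {
  cfg <- sim_config(n_fragments = 300, n_snps = 0, n_indels = 0, seed = 3)
  set.seed(99)
  fr <- make_fragments(cfg)
  set.seed(100)
  v <- induce_variants(fr, n_snps = 120, n_indels = 60)
  expect_equal(sum(v$vtype == "SNP"), 120)
  expect_equal(sum(v$vtype %in% c("INS", "DEL")), 60)
  expect_false(anyDuplicated(v$fragment_id) > 0)
  # alleles anchored per VCF convention
  snps <- v[vtype == "SNP"]
  expect_true(all(nchar(snps$ref_allele) == 1 & nchar(snps$alt_allele) == 1))
  expect_true(all(snps$ref_allele != snps$alt_allele))
  indels <- v[vtype != "SNP"]
  expect_true(all(substr(indels$ref_allele, 1, 1) ==
                    substr(indels$alt_allele, 1, 1)))
  ilen <- abs(nchar(indels$ref_allele) - nchar(indels$alt_allele))
  expect_true(all(ilen >= 1 & ilen <= 10))
  # ref alleles actually present on the fragment at the stated offset
  m <- match(v$fragment_id, fr$fragment_id)
  obs <- substr(fr$sequence[m], v$offset0 + 1, v$offset0 + nchar(v$ref_allele))
  expect_identical(obs, v$ref_allele)
  # empty and over-constrained cases
  expect_equal(nrow(induce_variants(fr[1:10], 0, 0)), 0)
  expect_error(induce_variants(fr[1:5], 6, 0), "at most one variant")
})

test_that("population genotypes follow Hardy-Weinberg proportions", {
  v <- data.table::data.table(fragment_id = "fragA", offset0 = 20L,
                              vtype = "SNP", ref_allele = "A",
                              alt_allele = "C", maf = NA_real_)
  set.seed(5)
  pg <- sample_population_genotypes(v, n_individuals = 10000,
                                    maf_range = c(0.5, 0.5))
  het_frac <- mean(pg$genotypes$genotype == "het")
  expect_lt(abs(het_frac - 0.5), 0.015)
  hom_alt <- mean(pg$genotypes$genotype == "homAlt")
  expect_lt(abs(hom_alt - 0.25), 0.015)
  # one row per (variant, individual); n = 1 edge case
  set.seed(6)
  pg1 <- sample_population_genotypes(v, n_individuals = 1)
  expect_equal(nrow(pg1$genotypes), 1)
})

test_that("every variant has at least one carrier", {
  cfg <- sim_config(n_fragments = 150, n_snps = 60, n_indels = 20,
                    n_individuals = 4, maf_range = c(0.1, 0.2), seed = 8)
  sim <- simulate_gbs(cfg)
  carriers <- sim$genotypes[, .(n = sum(genotype != "homRef")),
                            by = fragment_id]
  expect_true(all(carriers$n >= 1))
  expect_equal(nrow(carriers), 80)
})

test_that("error-free reads are exact haplotype prefixes and depths respect the range", {
  cfg <- sim_config(n_fragments = 30, n_snps = 0, n_indels = 0,
                    n_individuals = 2, error_rate = 0, seed = 21)
  sim <- simulate_gbs(cfg)
  m <- match(sim$reads$fragment_id, sim$fragments$fragment_id)
  expect_identical(sim$reads$sequence,
                   substr(sim$fragments$sequence[m], 1, cfg$read_length))
  depth <- sim$reads[, .N, by = .(individual_id, fragment_id)]
  expect_true(all(depth$N >= 20 & depth$N <= 30))
  expect_equal(nrow(depth), 60) # every (individual, fragment) covered
})

test_that("observed per-base error rate matches the configured 1.1%", {
  cfg <- sim_config(n_fragments = 40, n_snps = 0, n_indels = 0,
                    n_individuals = 2, error_rate = 0.011, seed = 31)
  sim <- simulate_gbs(cfg)
  m <- match(sim$reads$fragment_id, sim$fragments$fragment_id)
  truth <- substr(sim$fragments$sequence[m], 1, cfg$read_length)
  nb <- sum(nchar(sim$reads$sequence))
  expect_gt(nb, 1e5)
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$reads$sequence, truth))
  expect_lt(abs(mism / nb - 0.011), 0.001)
})

test_that("same seed gives byte-identical simulations, different seed differs", {
  cfg <- sim_config(n_fragments = 50, n_snps = 10, n_indels = 5,
                    n_individuals = 3, seed = 77)
  s1 <- simulate_gbs(cfg)
  s2 <- simulate_gbs(cfg)
  expect_identical(s1$reads$sequence, s2$reads$sequence)
  expect_identical(s1$variants, s2$variants)
  s3 <- simulate_gbs(sim_config(n_fragments = 50, n_snps = 10, n_indels = 5,
                                n_individuals = 3, seed = 78))
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("read counts are conserved in the manifest and ids are traceable", {
  sim <- tiny_sim(seed = 13)
  expect_equal(sum(sim$manifest$n_reads), nrow(sim$reads))
  parts <- data.table::tstrsplit(sim$reads$read_id, ":", fixed = TRUE)
  expect_identical(parts[[1]], sim$reads$individual_id)
  expect_identical(parts[[2]], sim$reads$fragment_id)
  expect_false(anyDuplicated(sim$reads$read_id) > 0)
})

test_that("truth completeness: with no error every carried alt allele reaches the reads", {
  cfg <- sim_config(n_fragments = 80, n_snps = 30, n_indels = 10,
                    n_individuals = 5, error_rate = 0, seed = 41)
  sim <- simulate_gbs(cfg)
  v <- sim$variants
  for (i in seq_len(nrow(v))) {
    frag <- sim$fragments[fragment_id == v$fragment_id[i]]
    alt_hap <- gbsnp:::apply_variant(frag$sequence, v$offset0[i],
                                     v$ref_allele[i], v$alt_allele[i])
    alt_prefix <- substr(alt_hap, 1, cfg$read_length)
    carried <- sim$genotypes[fragment_id == v$fragment_id[i] &
                               genotype != "homRef"]
    reads_i <- sim$reads[fragment_id == v$fragment_id[i] &
                           individual_id %in% carried$individual_id]
    expect_true(alt_prefix %in% reads_i$sequence,
                label = paste("alt allele of", v$fragment_id[i], "in reads"))
  }
})

test_that("heterozygote allele balance is binomial(d, 0.5) on average", {
  cfg <- sim_config(n_fragments = 120, n_snps = 60, n_indels = 0,
                    n_individuals = 8, error_rate = 0,
                    maf_range = c(0.4, 0.5), seed = 55)
  sim <- simulate_gbs(cfg)
  hets <- sim$genotypes[genotype == "het"]
  v <- sim$variants
  m <- match(hets$fragment_id, v$fragment_id)
  frag_seq <- sim$fragments$sequence[match(hets$fragment_id,
                                           sim$fragments$fragment_id)]
  alt_frac <- mapply(function(ind, fid, fi) {
    reads_i <- sim$reads[individual_id == ind & fragment_id == fid]
    o <- v$offset0[fi]
    base <- substr(reads_i$sequence, o + 1, o + 1)
    mean(base == v$alt_allele[fi])
  }, hets$individual_id, hets$fragment_id, m)
  expect_gt(length(alt_frac), 100)
  expect_lt(abs(mean(alt_frac) - 0.5), 0.01)
})

test_that("paired mode emits R2 as the reverse complement of the fragment tail", {
  cfg <- sim_config(n_fragments = 10, n_snps = 0, n_indels = 0,
                    n_individuals = 1, error_rate = 0, read_mode = "paired",
                    seed = 61)
  sim <- simulate_gbs(cfg)
  expect_setequal(unique(sim$reads$mate), c("R1", "R2"))
  r2 <- sim$reads[mate == "R2"]
  frag <- sim$fragments$sequence[match(r2$fragment_id,
                                       sim$fragments$fragment_id)]
  tails <- substr(frag, nchar(frag) - cfg$read_length + 1, nchar(frag))
  expect_identical(r2$sequence, gbsnp:::revcomp(tails))
})
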