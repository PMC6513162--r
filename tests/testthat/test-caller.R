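# Genotyping rules, site-level calling, population filters, and the VCF /
# description / genotype-matrix writers.

make_bc <- function(...) {
  # build a 4 x n matrix of base counts from named vectors per individual,
  # e.g. make_bc(c(A = 10), c(A = 5, C = 6))
  cols <- list(...)
  m <- matrix(0L, 4, length(cols), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(cols)) m[names(cols[[i]]), i] <- as.integer(cols[[i]])
  m
}

test_that("genotype_individual applies the depth and fraction bands", {
  p <- caller_params()
  expect_identical(genotype_individual(25, 0, params = p), "homRef")
  expect_identical(genotype_individual(12, 13, params = p), "het")
  expect_identical(genotype_individual(2, 1, params = p), "missing") # depth floor
  expect_identical(genotype_individual(0, 30, params = p), "homAlt")
  # ambiguous zone between hom and het bands -> missing
  expect_identical(genotype_individual(20, 3, params = caller_params(
    min_minor_depth_het = 3, min_minor_frac_het = 0.2,
    max_minor_frac_hom = 0.1)), "missing")
  # vectorized
  expect_identical(genotype_individual(c(25, 12, 2), c(0, 13, 1), params = p),
                   c("homRef", "het", "missing"))
  expect_error(genotype_individual(-1, 5), "negative")
})

test_that("monomorphic and low-call-rate sites yield no call", {
  p <- caller_params()
  mono <- make_bc(c(A = 25), c(A = 22), c(A = 28))
  expect_null(call_site(mono, "A", p))
  # polymorphic but only 2 of 8 individuals deep enough: call rate 0.25 < 0.75
  cols <- c(list(c(A = 12, G = 13), c(A = 25)),
            replicate(6, c(A = 2), simplify = FALSE))
  low <- do.call(make_bc, cols)
  expect_null(call_site(low, "A", p))
  # same depths pass when the call-rate requirement is relaxed
  got <- call_site(low, "A", caller_params(min_call_rate = 0.2))
  expect_false(is.null(got))
})

test_that("call_site genotypes a clean SNP column correctly", {
  p <- caller_params()
  bc <- make_bc(c(A = 25), c(A = 12, G = 13), c(G = 24), c(A = 20), c(A = 9, G = 11))
  got <- call_site(bc, "A", p, centroid_id = "MR1", pos0 = 41L)
  expect_false(is.null(got))
  expect_identical(got$call$vtype, "SNP")
  expect_identical(got$call$ref_allele, "A")
  expect_identical(got$call$alt_allele, "G")
  expect_equal(got$call$pos1, 42L)
  expect_identical(got$genotypes$gt,
                   c("homRef", "het", "homAlt", "homRef", "het"))
  expect_equal(got$call$n_called, 5)
  expect_equal(got$call$n_het, 2)
  expect_equal(got$call$alt_frequency, (2 + 2 * 1) / 10)
})

test_that("a third allele above the noise floor drops the site as multi-allelic", {
  p <- caller_params()
  tri <- make_bc(c(A = 20, C = 10), c(A = 10, C = 10, G = 12), c(A = 20, C = 10))
  expect_null(call_site(tri, "A", p))
  # a third allele at error level does not
  ok <- make_bc(c(A = 20, C = 10), c(A = 10, C = 10, G = 2), c(A = 20, C = 10))
  expect_false(is.null(call_site(ok, "A", p)))
})

test_that("indel alleles are called against the spanning-reference support", {
  p <- caller_params()
  # 3 individuals; ind 2 het for a 2 bp deletion anchored at this column
  bc <- make_bc(c(A = 25), c(A = 24), c(A = 26))
  idl <- data.table::data.table(ref_allele = "ATT", alt_allele = "A",
                                ind = 2L, count = 12L)
  got <- call_site(bc, "A", p, indel_counts = idl)
  expect_false(is.null(got))
  expect_identical(got$call$vtype, "DEL")
  expect_identical(got$genotypes$gt, c("homRef", "het", "homRef"))
  expect_equal(got$genotypes$ad_alt, c(0L, 12L, 0L))
  expect_equal(got$genotypes$ad_ref, c(25L, 12L, 26L))
})

test_that("zero-error simulation gives >= 99% genotype concordance at called sites", {
  sim <- tiny_sim(seed = 211, n_fragments = 100, n_snps = 30, n_indels = 10,
                  n_individuals = 8, error_rate = 0)
  ps <- run_small_pipeline(sim)
  ev <- evaluate_calls(ps$calls, sim$variants, ps$mr, sim$fragments,
                       genotypes = sim$genotypes)
  expect_gte(ev$concordance, 0.99)
  expect_equal(ev$report$type1, 0)
})

test_that("tightening call rate or depth floor never increases the call count", {
  sim <- tiny_sim(seed = 223, n_fragments = 80, n_snps = 25, n_indels = 8,
                  n_individuals = 6)
  mr <- build_mock_reference(sim$reads)
  idx <- build_kmer_index(mr)
  aln <- align_reads(sim$reads, idx)
  pile <- make_pileup(aln, sim$reads, mr)
  n_calls <- function(...) nrow(call_population(pile, caller_params(...))$calls)
  base <- n_calls()
  expect_lte(n_calls(min_call_rate = 0.9), base)
  expect_lte(n_calls(min_depth_call = 15), base)
  expect_lte(n_calls(min_depth_call = 40), n_calls(min_depth_call = 15))
})

test_that("empty pileups give an empty, well-formed call set", {
  mrdt <- data.table::data.table(centroid_id = "MR1",
                                 sequence = random_dna(1, 150))
  reads <- data.table::data.table(read_id = "r1", individual_id = "ind01",
                                  sequence = random_dna(1, 150))
  aln <- data.table::data.table(read_id = "r1", individual_id = "ind01",
                                centroid_id = NA_character_, pos0 = NA_integer_,
                                cigar = NA_character_, strand = NA_character_,
                                edit = NA_integer_)
  pile <- make_pileup(aln, reads, mrdt)
  calls <- call_population(pile)
  expect_equal(nrow(calls$calls), 0)
  expect_equal(nrow(calls$genotypes), 0)
})

test_that("VCF output is well-formed for empty and populated call sets", {
  sim <- tiny_sim(seed = 227, n_fragments = 60, n_snps = 20, n_indels = 8,
                  n_individuals = 5, error_rate = 0)
  ps <- run_small_pipeline(sim)
  vcf_path <- tempfile(fileext = ".vcf")
  write_vcf(ps$calls, ps$mr, vcf_path)
  lines <- readLines(vcf_path)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(ps$calls$calls))
  fields <- strsplit(body, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 9 + length(ps$calls$individuals)))
  # ALT is a single allele everywhere (bi-allelism)
  alt <- vapply(fields, `[`, character(1), 5)
  expect_false(any(grepl(",", alt)))
  # parses with vcfR and round-trips GT content
  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(ps$calls$calls))
  # empty set: header-only file still parses
  empty <- gbsnp:::subset_calls(ps$calls, character(0))
  empty_path <- tempfile(fileext = ".vcf")
  write_vcf(empty, ps$mr, empty_path)
  ve <- vcfR::read.vcfR(empty_path, verbose = FALSE)
  expect_equal(nrow(ve@fix), 0)
})

test_that("deletion calls are left-anchored in the VCF (POS at anchor, REF longer)", {
  sim <- tiny_sim(seed = 229, n_fragments = 60, n_snps = 0, n_indels = 25,
                  n_individuals = 6, error_rate = 0)
  ps <- run_small_pipeline(sim)
  dels <- ps$calls$calls[vtype == "DEL"]
  expect_gt(nrow(dels), 0)
  expect_true(all(nchar(dels$ref_allele) > 1 & nchar(dels$alt_allele) == 1))
  expect_true(all(substr(dels$ref_allele, 1, 1) == dels$alt_allele))
  ins <- ps$calls$calls[vtype == "INS"]
  expect_gt(nrow(ins), 0)
  expect_true(all(nchar(ins$alt_allele) > 1 & nchar(ins$ref_allele) == 1))
})

test_that("description table matches the call set and its Z-scores", {
  sim <- tiny_sim(seed = 233, n_fragments = 50, n_snps = 15, n_indels = 5,
                  n_individuals = 6)
  ps <- run_small_pipeline(sim)
  fh <- filter_homologs(ps$calls)
  desc <- write_description(fh$retained)
  expect_equal(nrow(desc), nrow(fh$retained$calls))
  st <- homolog_z(fh$retained)
  m <- match(desc$variant_id, st$variant_id)
  expect_equal(desc$zscore, st$z[m])
  # pooled het depths reconcile with the genotype table
  hets <- fh$retained$genotypes[gt == "het",
                                .(r = sum(ad_ref)), by = variant_id]
  m2 <- match(hets$variant_id, desc$variant_id)
  expect_equal(desc$het_ref_depth[m2], hets$r)
  # genotype matrix mirrors the VCF content one-to-one
  gm_path <- tempfile(fileext = ".tsv")
  write_genotype_matrix(fh$retained, gm_path)
  gm <- data.table::fread(gm_path)
  expect_equal(nrow(gm), nrow(fh$retained$calls))
  expect_true(all(paste0(fh$retained$individuals, ".GT") %in% names(gm)))
})
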