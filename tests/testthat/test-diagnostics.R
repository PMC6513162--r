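# Homolog Z-score computation and filtering, allele-ratio distributions,
# and ploidy inference.

# Build a gbs_calls object directly from per-variant het depth pairs.
calls_from_hets <- function(ref_depths, alt_depths, ids = NULL) {
  nv <- length(ref_depths)
  ids <- ids %||% sprintf("MR1:%d:A:G", seq_len(nv))
  genos <- data.table::rbindlist(lapply(seq_len(nv), function(i) {
    r <- ref_depths[[i]]
    a <- alt_depths[[i]]
    data.table::data.table(
      variant_id = ids[i],
      individual_id = sprintf("ind%02d", seq_along(r)),
      gt = "het", ad_ref = as.integer(r), ad_alt = as.integer(a),
      dp = as.integer(r + a))
  }))
  calls <- data.table::data.table(
    variant_id = ids, centroid_id = "MR1", pos1 = seq_len(nv), vtype = "SNP",
    ref_allele = "A", alt_allele = "G", n_called = lengths(ref_depths),
    n_het = lengths(ref_depths), alt_frequency = 0.5, mean_depth = 20,
    zscore = NA_real_)
  structure(list(calls = calls, genotypes = genos,
                 individuals = sprintf("ind%02d",
                                       seq_len(max(lengths(ref_depths)))),
                 params = caller_params()),
            class = "gbs_calls")
}

test_that("homolog Z-score matches its closed form", {
  # pooled x = n/2 -> z = 0; (70, 30) -> z = 4; (27, 9) -> z = 3
  cl <- calls_from_hets(list(c(25, 25), c(40, 30), c(14, 13)),
                        list(c(30, 20), c(20, 10), c(5, 4)))
  st <- homolog_z(cl)
  expect_equal(st$z, c(0, 4, 3))
  expect_equal(st$x, c(50, 70, 27))
  expect_equal(st$n, c(100, 100, 36))
  expect_equal(st$ratio, c(0.5, 0.7, 0.75))
})

test_that("Z is antisymmetric under ref/alt swap and NA without heterozygotes", {
  cl <- calls_from_hets(list(c(40, 30)), list(c(20, 10)))
  cl_sw <- calls_from_hets(list(c(20, 10)), list(c(40, 30)))
  expect_equal(homolog_z(cl)$z, -homolog_z(cl_sw)$z)
  # no hets: flagged, never culled
  cl0 <- calls_from_hets(list(c(30, 30)), list(c(0, 0)))
  cl0$genotypes[, gt := "homRef"]
  st0 <- homolog_z(cl0)
  expect_false(st0$evaluable)
  expect_true(is.na(st0$z))
  fh0 <- filter_homologs(cl0)
  expect_equal(nrow(fh0$retained$calls), 1)
  expect_equal(nrow(fh0$culled$calls), 0)
})

test_that("filtering is strict at the threshold and uses |z|", {
  # z = 4.99: x - n/2 = 4.99 * sqrt(n/4) with n = 400 -> x = 249.9 ~ z just
  # below 5; use exact constructions instead
  n <- 400
  x_keep <- n / 2 + floor(4.99 * sqrt(n / 4)) # z = 4.9 < 5
  x_cull <- n / 2 - ceiling(6.2 * sqrt(n / 4)) # z <= -6.2
  cl <- calls_from_hets(list(c(x_keep, 0), c(x_cull, 0)),
                        list(c(n - x_keep, 0), c(n - x_cull, 0)))
  fh <- filter_homologs(cl, z_threshold = 5)
  expect_equal(nrow(fh$retained$calls), 1)
  expect_equal(nrow(fh$culled$calls), 1)
  expect_identical(fh$culled$calls$variant_id, cl$calls$variant_id[2])
  expect_lt(fh$stats$z[2], -5)
})

test_that("null calibration: honest 1:1 heterozygotes are essentially never culled", {
  set.seed(311)
  nv <- 20000
  n_het <- 12
  d <- sample(20:30, nv * n_het, replace = TRUE)
  alt <- rbinom(nv * n_het, d, 0.5)
  dt <- data.table::data.table(v = rep(seq_len(nv), each = n_het),
                               d = d, alt = alt)
  pooled <- dt[, .(x = sum(d - alt), n = sum(d)), by = v]
  z <- (pooled$x - pooled$n / 2) / sqrt(pooled$n / 4)
  expect_lt(mean(abs(z) > 5), 0.001)
})

test_that("Z classification agrees with the exact binomial tail for pooled n >= 100", {
  # the |z| > 5 rule corresponds to a two-sided exact binomial test at
  # alpha = 2 * pnorm(-5); for every n the two decision rules have
  # thresholds within one read count of each other, and classify every
  # off-boundary count identically
  alpha <- 2 * stats::pnorm(-5)
  for (n in c(100, 144, 256, 400, 625, 1024)) {
    x <- 0:n
    z <- (x - n / 2) / sqrt(n / 4)
    rej_z <- abs(z) > 5
    p_exact <- 2 * pmin(pbinom(x, n, 0.5), 1 - pbinom(x - 1, n, 0.5))
    rej_e <- p_exact < alpha
    thr_z <- min(x[rej_z & x > n / 2])
    thr_e <- min(x[rej_e & x > n / 2])
    expect_lte(abs(thr_z - thr_e), 1)
    boundary <- x %in% c(thr_z - 1, thr_z, n - thr_z, n - thr_z + 1)
    expect_identical(rej_z[!boundary], rej_e[!boundary],
                     label = paste("n =", n))
  }
})

test_that("a collapsed paralog locus is culled at |Z| > 5", {
  # Two fragments identical except one fixed difference; fragment A also
  # segregates a real SNP. Collapsing their reads 1:1 makes every
  # individual het at the fixed-difference site with balanced depths, but
  # systematically imbalanced (3:1) at the real variant site in hets.
  set.seed(317)
  fragA <- random_dna(1, 260)
  fragB <- fragA
  substr(fragB, 120, 120) <- "T"
  if (substr(fragA, 120, 120) == "T") substr(fragB, 120, 120) <- "G"
  var_pos <- 60L
  ref_base <- substr(fragA, var_pos + 1, var_pos + 1)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  n_ind <- 25L
  depth <- 25L
  gts <- rep(c("het", "homRef"), length.out = n_ind)
  altA <- fragA
  substr(altA, var_pos + 1, var_pos + 1) <- alt_base
  reads <- data.table::rbindlist(lapply(seq_len(n_ind), function(i) {
    hapA <- if (gts[i] == "het") c(fragA, altA) else c(fragA, fragA)
    segA <- sample(hapA, depth, replace = TRUE)
    segB <- rep(fragB, depth)
    data.table::data.table(
      read_id = sprintf("ind%02d:r%03d", i, seq_len(2 * depth)),
      individual_id = sprintf("ind%02d", i),
      sequence = substr(c(segA, segB), 1, 150))
  }))
  mr <- build_mock_reference(reads, individuals = reads$individual_id[1],
                             min_count = 2)
  expect_equal(nrow(mr$centroids), 1) # the two loci collapse
  idx <- build_kmer_index(mr)
  aln <- align_reads(reads, idx)
  pile <- make_pileup(aln, reads, mr)
  calls <- call_population(pile)
  fh <- filter_homologs(calls, z_threshold = 5)
  culled_pos <- fh$culled$calls$pos1
  expect_true((var_pos + 1L) %in% culled_pos)
})

test_that("allele ratios at het calls are centred on 0.5 in a diploid simulation", {
  sim <- tiny_sim(seed = 331, n_fragments = 150, n_snps = 60, n_indels = 0,
                  n_individuals = 8, error_rate = 0, maf_range = c(0.3, 0.5))
  ps <- run_small_pipeline(sim)
  ratios <- unlist(lapply(ps$calls$individuals, function(i)
    allele_ratio_distribution(ps$calls, i, min_depth = 10)))
  expect_gt(length(ratios), 100)
  expect_lt(abs(mean(ratios) - 0.5), 0.02)
  # min_depth larger than any depth empties the collection
  expect_length(allele_ratio_distribution(ps$calls, ps$calls$individuals[1],
                                          min_depth = 10000), 0)
})

test_that("ploidy inference recovers diploid and tetraploid ratio distributions", {
  set.seed(337)
  ok2 <- ok4 <- logical(100)
  for (r in 1:100) {
    d2 <- rbinom(200, 25, 0.5) / 25
    ok2[r] <- infer_ploidy(d2)$best_model == "diploid"
    comp <- sample(c(0.25, 0.5, 0.75), 200, replace = TRUE)
    d4 <- rbinom(200, 28, comp) / 28
    ok4[r] <- infer_ploidy(d4)$best_model == "tetraploid"
  }
  expect_gte(mean(ok2), 0.95)
  expect_gte(mean(ok4), 0.95)
})

test_that("too few ratios yield an insufficient-data report", {
  rep10 <- infer_ploidy(runif(10, 0.3, 0.7))
  expect_identical(rep10$status, "insufficient data")
  expect_true(is.na(rep10$best_model))
  expect_length(allele_ratio_distribution(
    calls_from_hets(list(c(10, 10)), list(c(10, 10))), "ind99"), 0)
})
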