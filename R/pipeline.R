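# End-to-end orchestration: simulate -> mock reference -> align -> call ->
# homolog filter -> ploidy -> evaluate, with all artifacts on disk and
# single-seed reproducibility.

#' Run the full pipeline
#'
#' Executes every stage with per-stage sub-seeds derived from `seed`, writes
#' each stage's artifacts under `out_dir`, and returns all intermediate
#' objects plus the evaluation report. Re-running with the same
#' configuration reproduces all outputs byte-identically.
#'
#' @param config a [run_config()] (or a path to a config file readable by
#'   [read_run_config()]).
#' @param quiet suppress stage messages.
#' @return list of class `gbs_run`: `config`, `sim`, `mr`, `alignments`,
#'   `pileup`, `calls` (pre-filter), `retained`, `culled`, `homolog_stats`,
#'   `ploidy`, `evaluation`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  scfg <- sim_config(
    n_fragments = config$sim.n_fragments,
    fragment_length_range = c(config$sim.fragment_length_min,
                              config$sim.fragment_length_max),
    n_snps = config$sim.n_snps, n_indels = config$sim.n_indels,
    max_indel_len = config$sim.max_indel_len,
    n_individuals = config$sim.n_individuals,
    depth_range = c(config$sim.depth_min, config$sim.depth_max),
    error_rate = config$sim.error_rate,
    read_length = config$sim.read_length, read_mode = config$sim.read_mode,
    maf_range = c(config$sim.maf_min, config$sim.maf_max),
    seed = config$seed)

  say("[simulate] %d fragments, %d SNPs + %d indels, %d individuals",
      scfg$n_fragments, scfg$n_snps, scfg$n_indels, scfg$n_individuals)
  sim <- simulate_gbs(scfg)
  sim_dir <- file.path(out, "sim")
  if (isTRUE(config$io.write_reads)) {
    write_simulation(sim, sim_dir, gzip = isTRUE(config$io.gzip))
  } else {
    dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(sim$variants, file.path(sim_dir, "truth_variants.tsv"), sep = "\t")
    fwrite(sim$genotypes, file.path(sim_dir, "truth_genotypes.tsv"), sep = "\t")
    fwrite(sim$manifest, file.path(sim_dir, "manifest.tsv"), sep = "\t")
  }
  say("[simulate] %s reads emitted", format(nrow(sim$reads), big.mark = ","))

  ind_sel <- config$mockref.individuals
  if (grepl("^[0-9]+$", ind_sel)) ind_sel <- as.integer(ind_sel)
  else if (grepl(",", ind_sel)) ind_sel <- strsplit(ind_sel, ",")[[1]]
  mr <- build_mock_reference(sim$reads, individuals = ind_sel,
                             identity_threshold = config$mockref.identity,
                             min_count = config$mockref.min_count)
  write_mock_reference(mr, file.path(out, "mockref.fasta"))
  fwrite(mr$clusters$members[, .(cluster, sequence_hash = cpp_seq_hash(sequence),
                                 count, identity)],
         file.path(out, "clusters.tsv"), sep = "\t")
  say("[mockref] %d centroids from %s", nrow(mr$centroids),
      paste(mr$selection, collapse = ","))

  idx <- build_kmer_index(mr, k = config$align.k)
  aln <- align_reads(sim$reads, idx,
                     max_mismatch_frac = config$align.max_mismatch_frac,
                     band = config$align.band)
  if (isTRUE(config$io.write_sam))
    write_sam(aln, sim$reads, mr, file.path(out, "alignments.sam"),
              quality_char = attr(sim$reads, "quality_char") %||% "I")
  n_mapped <- sum(!is.na(aln$centroid_id))
  say("[align] %s/%s reads mapped (%.1f%%)",
      format(n_mapped, big.mark = ","),
      format(nrow(aln), big.mark = ","), 100 * n_mapped / nrow(aln))

  pile <- make_pileup(aln, sim$reads, mr)
  params <- caller_params(
    min_depth_call = config$call.min_depth_call,
    min_minor_depth_het = config$call.min_minor_depth_het,
    min_minor_frac_het = config$call.min_minor_frac_het,
    max_minor_frac_hom = config$call.max_minor_frac_hom,
    min_call_rate = config$call.min_call_rate,
    min_alt_carriers = config$call.min_alt_carriers)
  calls <- call_population(pile, params)
  say("[call] %d variants", nrow(calls$calls))

  fh <- filter_homologs(calls, z_threshold = config$filter.z_threshold,
                        method = config$filter.z_method)
  write_homolog_stats(fh$stats, file.path(out, "homolog_stats.tsv"))
  write_vcf(fh$retained, mr, file.path(out, "variants.vcf"))
  write_vcf(fh$culled, mr, file.path(out, "variants_culled.vcf"))
  write_genotype_matrix(fh$retained, file.path(out, "genotype_matrix.tsv"))
  write_description(fh$retained, file.path(out, "variant_description.tsv"))
  say("[filter-homologs] retained %d, culled %d",
      nrow(fh$retained$calls), nrow(fh$culled$calls))

  ploidy <- infer_ploidy_all(fh$retained, min_depth = config$ploidy.min_depth)
  fwrite(ploidy$summary, file.path(out, "ploidy_report.tsv"), sep = "\t")

  ev <- evaluate_calls(fh$retained, sim$variants, mr, sim$fragments,
                       genotypes = sim$genotypes)
  write_evaluation(ev, file.path(out, "evaluation_report.tsv"))
  fwrite(ev$per_call, file.path(out, "validation.tsv"), sep = "\t")
  say("[evaluate] Type I %.1f%% | Type II %.1f%% | accuracy %.1f%%",
      ev$report$type1, ev$report$type2, ev$report$accuracy)

  cfg_path <- file.path(out, "run_config.txt")
  write_run_config(config, cfg_path)
  manifest <- c(sprintf("gbsnp_version = %s", utils::packageVersion("gbsnp")),
                sprintf("seed = %d", config$seed),
                sprintf("config_md5 = %s", unname(tools::md5sum(cfg_path))),
                sprintf("n_reads = %d", nrow(sim$reads)),
                sprintf("n_centroids = %d", nrow(mr$centroids)),
                sprintf("n_variants_retained = %d", nrow(fh$retained$calls)),
                sprintf("elapsed_sec = %.1f",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(manifest, file.path(out, "run_manifest.txt"))

  structure(list(config = config, sim = sim, mr = mr, alignments = aln,
                 pileup = pile, calls = calls, retained = fh$retained,
                 culled = fh$culled, homolog_stats = fh$stats,
                 ploidy = ploidy, evaluation = ev, out_dir = out),
            class = "gbs_run")
}

#' @export
print.gbs_run <- function(x, ...) {
  cat("gbsnp pipeline run\n")
  print(x$evaluation$report)
  invisible(x)
}
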