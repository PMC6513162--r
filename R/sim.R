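# GBS read simulator: fragment space, induced variants, population
# genotypes, and error-laden per-individual reads with full truth records.

#' Simulation configuration
#'
#' Bundles and validates all parameters of a GBS simulation. The defaults
#' describe the benchmark population used throughout the package
#' documentation: 100,000 unique fragments carrying 25,000 SNPs and 10,000
#' bi-allelic indels (at most one variant per fragment), 25 diploid
#' individuals sequenced with 150 bp single-end reads at 20-30x depth per
#' fragment and a 1.1% per-base substitution error rate.
#'
#' @param n_fragments number of unique GBS fragments.
#' @param fragment_length_range integer vector `c(min, max)` of fragment
#'   lengths in bp; the minimum must be at least `read_length`.
#' @param n_snps,n_indels number of SNP / bi-allelic indel variants to
#'   induce; their sum may not exceed `n_fragments`.
#' @param max_indel_len maximum indel length in bp.
#' @param n_individuals population size.
#' @param depth_range integer vector `c(min, max)`: per-(individual,
#'   fragment) read depth is uniform on this range.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param read_length read length in bp.
#' @param read_mode `"single"` or `"paired"`.
#' @param maf_range minor-allele frequencies are drawn uniformly from this
#'   interval in `(0, 0.5]`.
#' @param margin variants are placed at fragment offsets within
#'   `[margin, read_length - margin]` so single-end reads cover them with
#'   flanking sequence.
#' @param seed integer seed; every stage of the simulation derives its own
#'   sub-seed from it, so identical configurations reproduce byte-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_fragments = 100000L,
                       fragment_length_range = c(240L, 400L),
                       n_snps = 25000L, n_indels = 10000L,
                       max_indel_len = 10L,
                       n_individuals = 25L,
                       depth_range = c(20L, 30L),
                       error_rate = 0.011,
                       read_length = 150L,
                       read_mode = c("single", "paired"),
                       maf_range = c(0.1, 0.5),
                       margin = 10L,
                       seed = 1L) {
  read_mode <- match.arg(read_mode)
  cfg <- list(n_fragments = as.integer(n_fragments),
              fragment_length_range = as.integer(fragment_length_range),
              n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
              max_indel_len = as.integer(max_indel_len),
              n_individuals = as.integer(n_individuals),
              depth_range = as.integer(depth_range),
              error_rate = as.numeric(error_rate),
              read_length = as.integer(read_length),
              read_mode = read_mode,
              maf_range = as.numeric(maf_range),
              margin = as.integer(margin),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$n_fragments < 1) fail("n_fragments must be >= 1")
  if (cfg$n_snps < 0 || cfg$n_indels < 0) fail("variant counts must be >= 0")
  if (cfg$n_snps + cfg$n_indels > cfg$n_fragments)
    fail("n_snps + n_indels must not exceed n_fragments (one variant per fragment)")
  if (length(cfg$fragment_length_range) != 2 ||
      cfg$fragment_length_range[1] > cfg$fragment_length_range[2])
    fail("fragment_length_range must be c(min, max) with min <= max")
  if (cfg$fragment_length_range[1] < cfg$read_length)
    fail("fragment_length_range min must be >= read_length")
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] < 1 ||
      cfg$depth_range[1] > cfg$depth_range[2])
    fail("depth_range must be c(min, max) with 1 <= min <= max")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    fail("error_rate must be in [0, 1)")
  if (cfg$max_indel_len < 1) fail("max_indel_len must be >= 1")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    fail("maf_range must lie in (0, 0.5]")
  if (cfg$n_individuals < 1) fail("n_individuals must be >= 1")
  if (cfg$read_length <= 2 * cfg$margin)
    fail("read_length must exceed 2 * margin")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("GBS simulation config\n")
  cat(sprintf("  fragments: %d (%d-%d bp)\n", x$n_fragments,
              x$fragment_length_range[1], x$fragment_length_range[2]))
  cat(sprintf("  variants: %d SNPs + %d indels (<= %d bp)\n",
              x$n_snps, x$n_indels, x$max_indel_len))
  cat(sprintf("  population: %d individuals, depth %d-%dx, error %.3f\n",
              x$n_individuals, x$depth_range[1], x$depth_range[2],
              x$error_rate))
  cat(sprintf("  reads: %d bp %s-end, MAF U(%.2f, %.2f), seed %d\n",
              x$read_length, x$read_mode, x$maf_range[1], x$maf_range[2],
              x$seed))
  invisible(x)
}

#' Generate the fragment space
#'
#' Draws `n_fragments` pairwise-distinct random DNA fragments with i.i.d.
#' uniform base composition and lengths uniform over the configured range.
#' Uses the current RNG state; [simulate_gbs()] seeds it per stage.
#'
#' @param config a [sim_config()].
#' @return `data.table` with columns `fragment_id`, `sequence`.
#' @export
make_fragments <- function(config) {
  validate_sim_config(config)
  n <- config$n_fragments
  lens <- sample(config$fragment_length_range[1]:config$fragment_length_range[2],
                 n, replace = TRUE)
  seqs <- cpp_random_dna(lens)
  # random 240+ bp sequences are pairwise distinct w.h.p.; regenerate the
  # rare duplicate so uniqueness is guaranteed
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- cpp_random_dna(lens[dup])
  }
  data.table(fragment_id = fmt_ids("frag", n), sequence = seqs)
}

#' Induce SNP and indel variants
#'
#' Places at most one variant per fragment: `n_snps` substitutions and
#' `n_indels` bi-allelic insertions/deletions (lengths uniform on
#' `[1, max_indel_len]`, insertions and deletions equally likely). Alleles
#' follow the VCF left-anchored convention and are left-normalized against
#' the fragment. Offsets are restricted to
#' `[margin, read_length - margin]` so single-end reads cover every variant.
#'
#' @param fragments output of [make_fragments()].
#' @param n_snps,n_indels,max_indel_len see [sim_config()].
#' @param read_length,margin placement window parameters.
#' @return `data.table` with columns `fragment_id`, `offset0` (0-based),
#'   `vtype` (`SNP`/`INS`/`DEL`), `ref_allele`, `alt_allele`, `maf`
#'   (`NA` until [sample_population_genotypes()] draws frequencies).
#' @export
induce_variants <- function(fragments, n_snps, n_indels, max_indel_len = 10L,
                            read_length = 150L, margin = 10L) {
  n_snps <- as.integer(n_snps); n_indels <- as.integer(n_indels)
  if (n_snps + n_indels > nrow(fragments))
    stop("n_snps + n_indels exceeds the number of fragments ",
         "(at most one variant per fragment)", call. = FALSE)
  nv <- n_snps + n_indels
  out <- data.table(fragment_id = character(0), offset0 = integer(0),
                    vtype = character(0), ref_allele = character(0),
                    alt_allele = character(0), maf = numeric(0))
  if (nv == 0) return(out)
  rows <- sample.int(nrow(fragments), nv)
  seqs <- fragments$sequence[rows]
  vtype <- c(rep("SNP", n_snps),
             sample(c("INS", "DEL"), n_indels, replace = TRUE))
  # keep ref alleles (anchor + up to max_indel_len) inside the covered window
  off_hi <- read_length - margin - max_indel_len - 1L
  offs <- sample(margin:off_hi, nv, replace = TRUE)
  lens <- ifelse(vtype == "SNP", 0L,
                 sample.int(max_indel_len, nv, replace = TRUE))
  ref <- alt <- character(nv)
  for (i in seq_len(nv)) {
    s <- seqs[i]
    o <- offs[i]
    if (vtype[i] == "SNP") {
      rb <- substr(s, o + 1L, o + 1L)
      ab <- sample(setdiff(DNA_BASES, rb), 1L)
      ref[i] <- rb; alt[i] <- ab
    } else if (vtype[i] == "DEL") {
      ra <- substr(s, o + 1L, o + 1L + lens[i])
      nl <- cpp_left_normalize(s, o, ra, substr(ra, 1L, 1L))
      offs[i] <- nl$anchor0; ref[i] <- nl$ref; alt[i] <- nl$alt
    } else {
      anchor <- substr(s, o + 1L, o + 1L)
      ins <- paste(sample(DNA_BASES, lens[i], replace = TRUE), collapse = "")
      nl <- cpp_left_normalize(s, o, anchor, paste0(anchor, ins))
      offs[i] <- nl$anchor0; ref[i] <- nl$ref; alt[i] <- nl$alt
    }
  }
  data.table(fragment_id = fragments$fragment_id[rows], offset0 = offs,
             vtype = vtype, ref_allele = ref, alt_allele = alt,
             maf = NA_real_)[order(fragment_id)]
}

#' Assign population genotypes under Hardy-Weinberg proportions
#'
#' For each variant a minor-allele frequency is drawn uniformly from
#' `maf_range`; each individual's genotype is then drawn with probabilities
#' `maf^2` (homAlt), `2 maf (1 - maf)` (het) and `(1 - maf)^2` (homRef).
#' Variants that end up with no alt carrier are redrawn so every truth
#' variant is discoverable.
#'
#' @param variants output of [induce_variants()].
#' @param n_individuals population size.
#' @param maf_range see [sim_config()].
#' @return list with `genotypes` (`data.table`: `individual_id`,
#'   `fragment_id`, `genotype` in `homRef`/`het`/`homAlt`) and `variants`
#'   (the input with the drawn `maf` filled in).
#' @export
sample_population_genotypes <- function(variants, n_individuals,
                                        maf_range = c(0.1, 0.5)) {
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  inds <- fmt_ids("ind", n_individuals)
  nv <- nrow(variants)
  variants <- copy(variants)
  if (nv == 0) {
    return(list(genotypes = data.table(individual_id = character(0),
                                       fragment_id = character(0),
                                       genotype = character(0)),
                variants = variants))
  }
  mafs <- runif(nv, maf_range[1], maf_range[2])
  gcodes <- c("homRef", "het", "homAlt")
  draw <- function(maf) {
    sample(gcodes, n_individuals, replace = TRUE,
           prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
  }
  g <- matrix("", nrow = nv, ncol = n_individuals)
  for (i in seq_len(nv)) {
    gi <- draw(mafs[i])
    while (!any(gi != "homRef")) gi <- draw(mafs[i])
    g[i, ] <- gi
  }
  variants[, maf := mafs]
  genotypes <- data.table(
    individual_id = rep(inds, each = nv),
    fragment_id = rep(variants$fragment_id, n_individuals),
    genotype = as.vector(g))
  setkey(genotypes, individual_id, fragment_id)
  list(genotypes = genotypes[], variants = variants[])
}

# Apply a variant to a fragment sequence, returning the alt haplotype.
apply_variant <- function(seq, offset0, ref_allele, alt_allele) {
  stopifnot(substr(seq, offset0 + 1L, offset0 + nchar(ref_allele)) == ref_allele)
  paste0(substr(seq, 1L, offset0), alt_allele,
         substr(seq, offset0 + nchar(ref_allele) + 1L, nchar(seq)))
}

#' Generate sequencing reads
#'
#' For every (individual, fragment) pair a read depth is drawn uniformly
#' from `depth_range`; each read is copied from one of the individual's two
#' haplotypes (heterozygotes pick each with probability 0.5), truncated to
#' the first `read_length` bases (paired mode adds an R2 reverse-complement
#' of the last `read_length` bases), and each base is substituted
#' independently with probability `error_rate` by a uniformly chosen
#' different base. Base qualities are constant.
#'
#' @param fragments,variants,genotypes simulation tables (genotypes as
#'   returned by [sample_population_genotypes()]).
#' @param config a [sim_config()].
#' @return `data.table` with columns `read_id`, `individual_id`,
#'   `fragment_id`, `mate` (`none`/`R1`/`R2`), `sequence`; attribute
#'   `quality_char` holds the constant quality character and attribute
#'   `skipped` the number of reads dropped because a haplotype was shorter
#'   than `read_length`.
#' @export
generate_reads <- function(fragments, variants, genotypes, config) {
  nf <- nrow(fragments)
  inds <- sort(unique(genotypes$individual_id))
  if (length(inds) == 0) inds <- fmt_ids("ind", config$n_individuals)
  ni <- length(inds)
  hap_alt <- rep(NA_character_, nf)
  vidx <- match(variants$fragment_id, fragments$fragment_id)
  if (nrow(variants)) {
    hap_alt[vidx] <- mapply(apply_variant, fragments$sequence[vidx],
                            variants$offset0, variants$ref_allele,
                            variants$alt_allele, USE.NAMES = FALSE)
  }
  gm <- matrix(0L, nrow = nf, ncol = ni)
  if (nrow(genotypes)) {
    gi <- match(genotypes$fragment_id, fragments$fragment_id)
    gj <- match(genotypes$individual_id, inds)
    gm[cbind(gi, gj)] <- c(homRef = 0L, het = 1L, homAlt = 2L)[genotypes$genotype]
  }
  res <- cpp_generate_reads(fragments$sequence, hap_alt, gm,
                            config$depth_range[1], config$depth_range[2],
                            config$error_rate, config$read_length,
                            config$read_mode == "paired")
  reads <- data.table(individual_id = inds[res$ind],
                      fragment_id = fragments$fragment_id[res$frag],
                      mate = c("none", "R1", "R2")[res$mate + 1L],
                      sequence = res$sequence)
  serial <- reads[, rowid(individual_id, fragment_id, mate)]
  reads[, read_id := paste0(individual_id, ":", fragment_id, ":", serial)]
  setcolorder(reads, c("read_id", "individual_id", "fragment_id", "mate",
                       "sequence"))
  setattr(reads, "quality_char", "I")
  setattr(reads, "skipped", res$skipped)
  if (res$skipped > 0)
    warning(sprintf("%d reads skipped: haplotype shorter than read length",
                    res$skipped), call. = FALSE)
  reads[]
}

#' Run a full GBS simulation
#'
#' Executes [make_fragments()], [induce_variants()],
#' [sample_population_genotypes()] and [generate_reads()] with deterministic
#' per-stage sub-seeds derived from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   with [write_simulation()].
#' @return an object of class `gbs_sim`: list with `config`, `fragments`,
#'   `variants`, `genotypes`, `reads` and a per-individual `manifest`.
#' @export
simulate_gbs <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "fragments"))
  fragments <- make_fragments(config)
  set.seed(stage_seed(config$seed, "variants"))
  variants <- induce_variants(fragments, config$n_snps, config$n_indels,
                              config$max_indel_len, config$read_length,
                              config$margin)
  set.seed(stage_seed(config$seed, "genotypes"))
  pg <- sample_population_genotypes(variants, config$n_individuals,
                                    config$maf_range)
  set.seed(stage_seed(config$seed, "reads"))
  reads <- generate_reads(fragments, pg$variants, pg$genotypes, config)
  manifest <- reads[, .(n_reads = .N), by = individual_id][order(individual_id)]
  sim <- structure(list(config = config, fragments = fragments,
                        variants = pg$variants, genotypes = pg$genotypes,
                        reads = reads, manifest = manifest),
                   class = "gbs_sim")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' @export
print.gbs_sim <- function(x, ...) {
  cat(sprintf("GBS simulation: %d fragments, %d variants (%d SNP / %d indel), %d individuals, %s reads\n",
              nrow(x$fragments), nrow(x$variants),
              sum(x$variants$vtype == "SNP"), sum(x$variants$vtype != "SNP"),
              length(unique(x$manifest$individual_id)),
              format(nrow(x$reads), big.mark = ",")))
  invisible(x)
}

#' Write simulation artifacts to disk
#'
#' Emits `fragments.fasta`, per-individual FASTQ files
#' (`<individual>.R1.fastq`, plus `.R2` in paired mode),
#' `truth_variants.tsv`, `truth_genotypes.tsv`, `manifest.tsv` and a
#' `sim_config.txt` echo of the configuration.
#'
#' @param sim a `gbs_sim` object.
#' @param dir output directory (created if needed).
#' @param gzip compress FASTQ output.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(sim$fragments$sequence, sim$fragments$fragment_id),
              file.path(dir, "fragments.fasta"))
  qc <- attr(sim$reads, "quality_char") %||% "I"
  for (id in sim$manifest$individual_id) {
    sub <- sim$reads[individual_id == id]
    mates <- if (sim$config$read_mode == "paired") c("R1", "R2") else "none"
    for (m in mates) {
      msub <- sub[mate == m]
      suffix <- if (m == "R2") ".R2.fastq" else ".R1.fastq"
      if (gzip) suffix <- paste0(suffix, ".gz")
      write_fastq(setNames(msub$sequence, msub$read_id),
                  file.path(dir, paste0(id, suffix)), quality_char = qc)
    }
  }
  fwrite(sim$variants, file.path(dir, "truth_variants.tsv"), sep = "\t")
  fwrite(sim$genotypes, file.path(dir, "truth_genotypes.tsv"), sep = "\t")
  fwrite(sim$manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  cfg <- sim$config
  writeLines(c("# gbsnp simulation config",
               vapply(names(unclass(cfg)), function(k)
                 sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")),
                 character(1))),
             file.path(dir, "sim_config.txt"))
  invisible(dir)
}
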