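# Readers that reconstruct a gbs_calls object from the package's own VCF
# and genotype-matrix artifacts, so the homolog filter, ploidy inference
# and evaluation stages can run standalone on files.

GT_MAP <- c("0/0" = "homRef", "0/1" = "het", "1/0" = "het", "1/1" = "homAlt")

#' Read a gbsnp VCF back into a call set
#'
#' Parses a VCF 4.2 file with `GT:AD:DP` genotype fields (as written by
#' [write_vcf()]) into a `gbs_calls` object. Contig ids and lengths from the
#' header are attached as attribute `contigs`.
#'
#' @param path VCF path.
#' @return a `gbs_calls` object.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF file: ", path, call. = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  contig_lines <- hdr[startsWith(hdr, "##contig")]
  contigs <- data.table(
    centroid_id = sub(".*ID=([^,>]+).*", "\\1", contig_lines),
    length = as.integer(sub(".*length=([0-9]+).*", "\\1", contig_lines)))
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  if (!length(chrom_line)) stop("missing #CHROM header in ", path, call. = FALSE)
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  individuals <- if (length(cols) > 9) cols[10:length(cols)] else character(0)
  empty_calls <- data.table(variant_id = character(0),
                            centroid_id = character(0), pos1 = integer(0),
                            vtype = character(0), ref_allele = character(0),
                            alt_allele = character(0), n_called = integer(0),
                            n_het = integer(0), alt_frequency = numeric(0),
                            mean_depth = numeric(0), zscore = numeric(0))
  empty_g <- data.table(variant_id = character(0), individual_id = character(0),
                        gt = character(0), ad_ref = integer(0),
                        ad_alt = integer(0), dp = integer(0))
  out <- structure(list(calls = empty_calls, genotypes = empty_g,
                        individuals = individuals, params = caller_params()),
                   class = "gbs_calls")
  setattr(out, "contigs", contigs)
  if (!length(body)) return(out)
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  chrom <- f[[1]]; pos1 <- as.integer(f[[2]]); vid <- f[[3]]
  ref <- f[[4]]; alt <- f[[5]]; info <- f[[8]]
  vtype <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                  ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
  zs <- suppressWarnings(as.numeric(sub(".*ZSCORE=([-0-9.eE]+).*", "\\1", info)))
  glist <- lapply(seq_along(individuals), function(j) {
    cell <- f[[9 + j]]
    parts <- data.table::tstrsplit(cell, ":", fixed = TRUE)
    ad <- data.table::tstrsplit(parts[[2]], ",", fixed = TRUE)
    data.table(variant_id = vid, individual_id = individuals[j],
               gt = unname(ifelse(parts[[1]] %in% names(GT_MAP),
                                  GT_MAP[parts[[1]]], "missing")),
               ad_ref = suppressWarnings(as.integer(ad[[1]])),
               ad_alt = suppressWarnings(as.integer(ad[[2]])),
               dp = suppressWarnings(as.integer(parts[[3]])))
  })
  g <- rbindlist(glist)
  g[is.na(ad_ref), ad_ref := 0L]
  g[is.na(ad_alt), ad_alt := 0L]
  g[is.na(dp), dp := 0L]
  agg <- g[, .(n_called = sum(gt != "missing"), n_het = sum(gt == "het"),
               alt_frequency = {
                 nc <- sum(gt != "missing")
                 if (nc > 0) (sum(gt == "het") + 2 * sum(gt == "homAlt")) /
                   (2 * nc) else 0
               },
               mean_depth = mean(dp)), by = variant_id]
  calls <- data.table(variant_id = vid, centroid_id = chrom, pos1 = pos1,
                      vtype = vtype, ref_allele = ref, alt_allele = alt,
                      zscore = zs)
  calls <- merge(calls, agg, by = "variant_id", sort = FALSE)
  setcolorder(calls, names(empty_calls))
  out$calls <- calls
  out$genotypes <- g
  out
}

#' Read a genotype matrix back into a call set
#'
#' Parses the TSV written by [write_genotype_matrix()] (one variant per
#' row, per-individual `GT`/`AD`/`DP` column triplets) into a `gbs_calls`
#' object, so the matrix can be converted to VCF standalone.
#'
#' @param path genotype-matrix TSV path.
#' @return a `gbs_calls` object.
#' @export
read_genotype_matrix <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  ad_cols <- grep("\\.AD$", hdr, value = TRUE)
  m <- fread(path, sep = "\t",
             colClasses = setNames(rep("character", length(ad_cols)), ad_cols))
  m[, zscore := suppressWarnings(as.numeric(zscore))]
  m[, pos1 := as.integer(pos1)]
  inds <- sub("\\.GT$", "", grep("\\.GT$", names(m), value = TRUE))
  glist <- lapply(inds, function(i) {
    ad <- data.table::tstrsplit(m[[paste0(i, ".AD")]], ",", fixed = TRUE)
    data.table(variant_id = m$variant_id, individual_id = i,
               gt = m[[paste0(i, ".GT")]],
               ad_ref = as.integer(ad[[1]]), ad_alt = as.integer(ad[[2]]),
               dp = as.integer(m[[paste0(i, ".DP")]]))
  })
  g <- rbindlist(glist)
  agg <- g[, .(n_called = sum(gt != "missing"), n_het = sum(gt == "het"),
               alt_frequency = {
                 nc <- sum(gt != "missing")
                 if (nc > 0) (sum(gt == "het") + 2 * sum(gt == "homAlt")) /
                   (2 * nc) else 0
               },
               mean_depth = mean(dp)), by = variant_id]
  calls <- merge(m[, .(variant_id, centroid_id, pos1, vtype, ref_allele,
                       alt_allele, zscore)],
                 agg, by = "variant_id", sort = FALSE)
  setcolorder(calls, c("variant_id", "centroid_id", "pos1", "vtype",
                       "ref_allele", "alt_allele", "n_called", "n_het",
                       "alt_frequency", "mean_depth", "zscore"))
  structure(list(calls = calls, genotypes = g, individuals = inds,
                 params = caller_params()),
            class = "gbs_calls")
}
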