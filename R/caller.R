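# Bi-allelic SNP/indel calling from pileups: within-individual depth rules
# plus across-population polymorphism filters, and the genotype-matrix /
# description / VCF writers.

#' Caller thresholds
#'
#' Within-individual and across-population calling parameters. The defaults
#' are conservative for 20-30x GBS depth and fully configurable; they are
#' not canonical values of any published pipeline.
#'
#' @param min_depth_call minimum total depth for an individual to be
#'   genotyped (else missing).
#' @param min_minor_depth_het minimum minor-allele reads to call a
#'   heterozygote.
#' @param min_minor_frac_het minimum minor-allele fraction for a
#'   heterozygote.
#' @param max_minor_frac_hom maximum minor-allele fraction for a homozygote;
#'   individuals between the het and hom bands are set missing (ambiguous).
#' @param min_call_rate minimum fraction of individuals genotyped for a
#'   variant to be emitted.
#' @param min_alt_carriers minimum called individuals carrying the alt
#'   allele.
#' @param noise_floor_reads,noise_floor_frac a site is dropped as
#'   multi-allelic when a third allele exceeds
#'   `max(noise_floor_reads, noise_floor_frac * pooled depth)`.
#' @return object of class `caller_params`.
#' @export
caller_params <- function(min_depth_call = 6L, min_minor_depth_het = 3L,
                          min_minor_frac_het = 0.20,
                          max_minor_frac_hom = 0.10,
                          min_call_rate = 0.75, min_alt_carriers = 1L,
                          noise_floor_reads = 2L, noise_floor_frac = 0.05) {
  p <- list(min_depth_call = as.integer(min_depth_call),
            min_minor_depth_het = as.integer(min_minor_depth_het),
            min_minor_frac_het = as.numeric(min_minor_frac_het),
            max_minor_frac_hom = as.numeric(max_minor_frac_hom),
            min_call_rate = as.numeric(min_call_rate),
            min_alt_carriers = as.integer(min_alt_carriers),
            noise_floor_reads = as.integer(noise_floor_reads),
            noise_floor_frac = as.numeric(noise_floor_frac))
  stopifnot(p$min_depth_call >= 0, p$min_minor_depth_het >= 0,
            p$min_minor_frac_het >= 0, p$min_minor_frac_het <= 1,
            p$max_minor_frac_hom >= 0, p$max_minor_frac_hom <= 1,
            p$min_call_rate >= 0, p$min_call_rate <= 1)
  structure(p, class = "caller_params")
}

#' Genotype one individual from allele depths
#'
#' With primary depth `p = max(ref, alt)` and secondary `s = min(ref, alt)`:
#' missing when total depth is below `min_depth_call`; heterozygous when
#' `s >= min_minor_depth_het` and `s/(p+s) >= min_minor_frac_het`;
#' homozygous for the primary allele when `s/(p+s) <= max_minor_frac_hom`;
#' otherwise missing (evidence between the het and hom bands is treated as
#' unreliable rather than forced).
#'
#' @param ref_depth,alt_depth reads supporting the site's ref / alt allele
#'   (vectorized).
#' @param dp total depth at the site (defaults to `ref_depth + alt_depth`).
#' @param params a [caller_params()].
#' @return character vector over `homRef`/`het`/`homAlt`/`missing`.
#' @export
genotype_individual <- function(ref_depth, alt_depth, dp = NULL,
                                params = caller_params()) {
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("negative allele depths", call. = FALSE)
  if (is.null(dp)) dp <- ref_depth + alt_depth
  p <- pmax(ref_depth, alt_depth)
  s <- pmin(ref_depth, alt_depth)
  tot <- p + s
  fr <- ifelse(tot > 0, s / tot, NA_real_)
  gt <- rep("missing", length(p))
  ok <- dp >= params$min_depth_call & tot > 0
  het <- ok & s >= params$min_minor_depth_het & fr >= params$min_minor_frac_het
  hom <- ok & !het & fr <= params$max_minor_frac_hom
  gt[het] <- "het"
  gt[hom & ref_depth >= alt_depth] <- "homRef"
  gt[hom & alt_depth > ref_depth] <- "homAlt"
  gt
}

# Evaluate a single pileup column. base_counts: 4 x n_ind matrix (rows
# A,C,G,T); indel_counts: data.table(ref_allele, alt_allele, ind, count)
# with ind as column index. Returns NULL or list(call, genotypes).
site_eval <- function(base_counts, ref_base, pos0, centroid_id, individuals,
                      indel_counts, params) {
  ni <- ncol(base_counts)
  dp <- colSums(base_counts)
  refi <- match(ref_base, DNA_BASES)
  if (is.na(refi)) return(NULL)
  ind_indel_tot <- numeric(ni)
  indel_alleles <- list()
  if (!is.null(indel_counts) && nrow(indel_counts)) {
    keys <- paste(indel_counts$ref_allele, indel_counts$alt_allele, sep = ">")
    for (k in unique(keys)) {
      sub <- indel_counts[keys == k, ]
      v <- numeric(ni)
      v[sub$ind] <- sub$count
      indel_alleles[[k]] <- v
      ind_indel_tot <- ind_indel_tot + v
    }
  }
  ref_support <- pmax(base_counts[refi, ] - ind_indel_tot, 0)
  perind <- vector("list", 4 + length(indel_alleles))
  key <- character(length(perind))
  kind <- character(length(perind))
  for (b in 1:4) {
    perind[[b]] <- if (b == refi) ref_support else base_counts[b, ]
    key[b] <- DNA_BASES[b]
    kind[b] <- "base"
  }
  if (length(indel_alleles)) {
    ks <- names(indel_alleles)
    for (i in seq_along(ks)) {
      perind[[4 + i]] <- indel_alleles[[ks[i]]]
      key[4 + i] <- ks[i]
      kind[4 + i] <- "indel"
    }
  }
  pooled <- vapply(perind, sum, numeric(1))
  keep <- pooled > 0
  if (sum(keep) < 2) return(NULL)
  ord <- order(-pooled, key)
  ord <- ord[keep[ord]]
  top <- ord[1:2]
  # the site must be ref allele vs one alternative
  is_ref <- kind[top] == "base" & key[top] == ref_base
  if (!any(is_ref)) return(NULL)
  ref_slot <- top[is_ref][1]
  alt_slot <- setdiff(top, ref_slot)[1]
  # third-allele noise floor
  rest <- setdiff(ord, c(ref_slot, alt_slot))
  floor_ <- max(params$noise_floor_reads, params$noise_floor_frac * sum(dp))
  if (length(rest) && any(pooled[rest] > floor_)) return(NULL)

  if (kind[alt_slot] == "base") {
    vtype <- "SNP"
    ref_allele <- ref_base
    alt_allele <- key[alt_slot]
    site_pos0 <- pos0
  } else {
    parts <- strsplit(key[alt_slot], ">", fixed = TRUE)[[1]]
    ref_allele <- parts[1]
    alt_allele <- parts[2]
    vtype <- if (nchar(ref_allele) > nchar(alt_allele)) "DEL" else "INS"
    site_pos0 <- pos0
  }
  r <- perind[[ref_slot]]
  a <- perind[[alt_slot]]
  gt <- genotype_individual(r, a, dp, params)
  n_called <- sum(gt != "missing")
  if (n_called / ni < params$min_call_rate) return(NULL)
  carriers <- sum(gt %in% c("het", "homAlt"))
  if (carriers < params$min_alt_carriers) return(NULL)
  n_het <- sum(gt == "het")
  alt_freq <- (n_het + 2 * sum(gt == "homAlt")) / (2 * n_called)
  if (alt_freq == 0) return(NULL)
  vid <- sprintf("%s:%d:%s:%s", centroid_id, site_pos0 + 1L, ref_allele,
                 alt_allele)
  list(call = data.table(variant_id = vid, centroid_id = centroid_id,
                         pos1 = site_pos0 + 1L, vtype = vtype,
                         ref_allele = ref_allele, alt_allele = alt_allele,
                         n_called = n_called, n_het = n_het,
                         alt_frequency = alt_freq, mean_depth = mean(dp),
                         zscore = NA_real_),
       genotypes = data.table(variant_id = vid, individual_id = individuals,
                              gt = gt, ad_ref = as.integer(round(r)),
                              ad_alt = as.integer(round(a)),
                              dp = as.integer(dp)))
}

#' Call a variant at one pileup column
#'
#' Determines the population-wide top-two alleles (pooled depth), drops the
#' site when a third allele exceeds the noise floor (multi-allelic) or when
#' the centroid base is not among the top two, genotypes every individual
#' with [genotype_individual()], and retains the site only if the call rate,
#' alt-carrier and both-alleles-observed conditions hold.
#'
#' @param base_counts 4 x n-individual integer matrix of base depths
#'   (rows A, C, G, T) at the column.
#' @param ref_base the centroid base at the column.
#' @param params a [caller_params()].
#' @param indel_counts optional `data.table` with `ref_allele`,
#'   `alt_allele`, `ind` (individual column index), `count`: left-anchored
#'   indel alleles anchored at this column.
#' @param centroid_id,pos0 site coordinates for labelling.
#' @param individuals individual ids (defaults to column count).
#' @return `NULL` for a non-variant site, else list with one-row `call`
#'   `data.table` and per-individual `genotypes`.
#' @export
call_site <- function(base_counts, ref_base, params = caller_params(),
                      indel_counts = NULL, centroid_id = "centroid",
                      pos0 = 0L, individuals = NULL) {
  if (is.null(individuals))
    individuals <- colnames(base_counts) %||% fmt_ids("ind", ncol(base_counts))
  site_eval(base_counts, ref_base, as.integer(pos0), centroid_id,
            individuals, indel_counts, params)
}

#' Call variants across the population
#'
#' Applies [call_site()] over every polymorphic column of every centroid.
#' Candidate columns are those where some individual shows at least
#' `min_minor_depth_het` reads of a non-centroid base, plus every column
#' anchoring an indel allele with at least that much pooled support —
#' a necessary condition for any call, so the scan is lossless.
#'
#' @param pileup a [make_pileup()] object.
#' @param params a [caller_params()].
#' @return object of class `gbs_calls`: `calls` (`data.table`, one row per
#'   variant), `genotypes` (long `data.table`, one row per variant x
#'   individual), `individuals`, `params`.
#' @export
call_population <- function(pileup, params = caller_params()) {
  inds <- pileup$individuals
  ni <- length(inds)
  idl <- pileup$indels
  has_idl <- !is.null(idl) && nrow(idl) > 0
  if (has_idl) {
    idl <- copy(idl)
    idl[, ind := match(individual_id, inds)]
    setkey(idl, centroid_id)
  }
  calls <- list()
  genos <- list()
  for (ci in seq_along(pileup$centroid_id)) {
    cid <- pileup$centroid_id[ci]
    seqc <- strsplit(pileup$sequences[ci], "", fixed = TRUE)[[1]]
    L <- length(seqc)
    refi <- match(seqc, DNA_BASES)
    mx <- pileup$maxind[[ci]]
    mx[cbind(refi, seq_len(L))] <- 0L
    colmax <- pmax(mx[1, ], mx[2, ], mx[3, ], mx[4, ])
    cand <- which(colmax >= params$min_minor_depth_het) - 1L
    idl_c <- NULL
    if (has_idl && cid %in% idl$centroid_id) {
      idl_c <- idl[J(cid)]
      pooled_i <- idl_c[, .(n = sum(count)), by = .(pos0, ref_allele, alt_allele)]
      cand <- sort(unique(c(cand,
                            pooled_i[n >= params$min_minor_depth_het]$pos0)))
    }
    if (!length(cand)) next
    arr <- pileup$counts[[ci]]
    for (j0 in cand) {
      bc <- matrix(arr[, j0 + 1L, ], nrow = 4L)
      ic <- if (!is.null(idl_c)) idl_c[pos0 == j0] else NULL
      res <- site_eval(bc, seqc[j0 + 1L], j0, cid, inds, ic, params)
      if (!is.null(res)) {
        calls[[length(calls) + 1L]] <- res$call
        genos[[length(genos) + 1L]] <- res$genotypes
      }
    }
  }
  calls <- if (length(calls)) rbindlist(calls) else
    data.table(variant_id = character(0), centroid_id = character(0),
               pos1 = integer(0), vtype = character(0),
               ref_allele = character(0), alt_allele = character(0),
               n_called = integer(0), n_het = integer(0),
               alt_frequency = numeric(0), mean_depth = numeric(0),
               zscore = numeric(0))
  genos <- if (length(genos)) rbindlist(genos) else
    data.table(variant_id = character(0), individual_id = character(0),
               gt = character(0), ad_ref = integer(0), ad_alt = integer(0),
               dp = integer(0))
  structure(list(calls = calls, genotypes = genos, individuals = inds,
                 params = params),
            class = "gbs_calls")
}

#' @export
print.gbs_calls <- function(x, ...) {
  cat(sprintf("%d variant calls (%d SNP, %d INS, %d DEL) over %d individuals\n",
              nrow(x$calls), sum(x$calls$vtype == "SNP"),
              sum(x$calls$vtype == "INS"), sum(x$calls$vtype == "DEL"),
              length(x$individuals)))
  invisible(x)
}

# subset a gbs_calls object by variant ids
subset_calls <- function(calls, ids) {
  structure(list(calls = calls$calls[variant_id %in% ids],
                 genotypes = calls$genotypes[variant_id %in% ids],
                 individuals = calls$individuals, params = calls$params),
            class = "gbs_calls")
}

gt_to_vcf <- function(gt) {
  c(homRef = "0/0", het = "0/1", homAlt = "1/1", missing = "./.")[gt]
}

#' Write calls as VCF 4.2
#'
#' One line per bi-allelic variant: `CHROM` is the centroid id, `POS`
#' 1-based, indel alleles left-anchored; `FORMAT` is `GT:AD:DP`; `INFO`
#' carries `NS` (genotyped individuals), `AF` (alt frequency over called
#' genotypes) and `ZSCORE` (homolog statistic, `.` when not evaluable).
#'
#' @param calls a `gbs_calls` object.
#' @param mr the `mock_reference` (provides contig lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, mr, path) {
  centroids <- if (inherits(mr, "mock_reference")) mr$centroids else mr
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=gbsnp-", utils::packageVersion("gbsnp")),
           sprintf("##contig=<ID=%s,length=%d>", centroids$centroid_id,
                   nchar(centroids$sequence)),
           "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of genotyped samples\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency over called genotypes\">",
           "##INFO=<ID=ZSCORE,Number=1,Type=Float,Description=\"Homolog allele-depth Z-score pooled over heterozygotes\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depths for ref and alt alleles\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", calls$individuals), collapse = "\t"))
  if (nrow(calls$calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  cc <- copy(calls$calls)[order(centroid_id, pos1)]
  g <- calls$genotypes
  g <- g[, .(variant_id, individual_id,
             field = paste0(gt_to_vcf(gt), ":", ad_ref, ",", ad_alt, ":", dp))]
  wide <- dcast(g, variant_id ~ individual_id, value.var = "field",
                fill = ".:.:.")
  wide <- wide[match(cc$variant_id, variant_id)]
  info <- sprintf("NS=%d;AF=%s;ZSCORE=%s", cc$n_called,
                  formatC(cc$alt_frequency, format = "g", digits = 4),
                  ifelse(is.na(cc$zscore), ".",
                         formatC(cc$zscore, format = "f", digits = 3)))
  fixed <- paste(cc$centroid_id, cc$pos1, cc$variant_id, cc$ref_allele,
                 cc$alt_allele, ".", "PASS", info, "GT:AD:DP", sep = "\t")
  body <- do.call(paste,
                  c(list(fixed),
                    lapply(calls$individuals, function(i) wide[[i]]),
                    sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the variant description table
#'
#' One row per variant with the summary statistics users need to design
#' downstream filters: coordinates, alleles, call counts, alt frequency,
#' mean depth, pooled heterozygote ref/alt depths, and the homolog Z-score.
#'
#' @param calls a `gbs_calls` object.
#' @param path output path.
#' @return the description `data.table`, invisibly; written as TSV when
#'   `path` is given.
#' @export
write_description <- function(calls, path = NULL) {
  cc <- copy(calls$calls)
  hets <- calls$genotypes[gt == "het",
                          .(het_ref_depth = sum(ad_ref),
                            het_alt_depth = sum(ad_alt)), by = variant_id]
  desc <- merge(cc, hets, by = "variant_id", all.x = TRUE, sort = FALSE)
  desc[is.na(het_ref_depth), `:=`(het_ref_depth = 0L, het_alt_depth = 0L)]
  setorder(desc, centroid_id, pos1)
  if (!is.null(path)) fwrite(desc, path, sep = "\t")
  invisible(desc[])
}

#' Write the genotype matrix
#'
#' One variant per row; per individual a `GT`/`AD`/`DP` column triplet. The
#' layout mirrors the VCF content one-to-one, so VCF conversion is a pure
#' format change.
#'
#' @param calls a `gbs_calls` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(calls, path) {
  cc <- copy(calls$calls)[order(centroid_id, pos1)]
  base <- cc[, .(variant_id, centroid_id, pos1, vtype, ref_allele, alt_allele,
                 zscore)]
  g <- calls$genotypes
  for (i in calls$individuals) {
    gi <- g[individual_id == i][match(base$variant_id, variant_id)]
    base[, paste0(i, ".GT") := gi$gt]
    base[, paste0(i, ".AD") := paste0(gi$ad_ref, ",", gi$ad_alt)]
    base[, paste0(i, ".DP") := gi$dp]
  }
  fwrite(base, path, sep = "\t")
  invisible(path)
}
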