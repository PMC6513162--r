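# Format readers/writers (FASTA, FASTQ, SAM) and the flat-text run
# configuration. FASTA/FASTQ parsing is delegated to Biostrings.

#' Read a FASTA file
#'
#' Accepts wrapped and unwrapped records; lowercase bases are normalized to
#' uppercase (with a message).
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return `data.table` with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("failed to parse FASTA '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  seqs <- as.character(x)
  if (any(grepl("[acgtn]", seqs))) {
    message("read_fasta: lowercase bases normalized to uppercase in ", path)
    seqs <- toupper(seqs)
  }
  data.table(id = sub("\\s.*$", "", names(x)), sequence = unname(seqs))
}

#' Write a FASTA file
#'
#' @param x named character vector of sequences, or a `data.table`/list with
#'   `id` and `sequence` columns.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record parsing: a truncated file, a missing `@`/`+`
#' marker, or a sequence/quality length mismatch raises an error naming the
#' offending record.
#'
#' @param path 4-line-per-record FASTQ, optionally gzip-compressed.
#' @return `data.table` with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  bad <- function(rec, why) stop("failed to parse FASTQ '", path,
                                 "': record ", rec, ": ", why, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0)
    return(data.table(read_id = character(0), sequence = character(0),
                      quality = character(0)))
  if (length(lines) %% 4 != 0)
    bad(length(lines) %/% 4 + 1, "truncated (line count not a multiple of 4)")
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  chk <- which(!startsWith(hdr, "@"))
  if (length(chk)) bad(chk[1], "missing '@' header")
  chk <- which(!startsWith(plus, "+"))
  if (length(chk)) bad(chk[1], "missing '+' separator")
  chk <- which(nchar(qual) != nchar(seqs))
  if (length(chk)) bad(chk[1], "sequence/quality length mismatch")
  data.table(read_id = sub("\\s.*$", "", sub("^@", "", hdr)),
             sequence = seqs, quality = qual)
}

#' Write a FASTQ file
#'
#' @param x named character vector of sequences (names become read ids), or
#'   a `data.table` with `read_id`, `sequence` and optionally `quality`
#'   columns.
#' @param path output path; a `.gz` suffix triggers compression.
#' @param quality_char constant quality character used when no per-read
#'   qualities are supplied.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, quality_char = "I") {
  if (is.data.frame(x)) {
    ids <- x$read_id
    seqs <- x$sequence
    quals <- if ("quality" %in% names(x)) x$quality else NULL
  } else {
    ids <- names(x)
    seqs <- unname(x)
    quals <- NULL
  }
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n)
      strrep(quality_char, n), character(1))
  dna <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a SAM 1.x file with `@SQ` lines from the mock reference and one
#' `@RG` read group per individual. Unmapped reads get flag 4.
#'
#' @param alignments output of [align_reads()].
#' @param reads the read table that was aligned (provides sequences).
#' @param mr the [build_mock_reference()] object (or a `data.table` with
#'   `centroid_id`, `sequence`).
#' @param path output path.
#' @param quality_char constant base quality.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, mr, path, quality_char = "I") {
  centroids <- if (inherits(mr, "mock_reference")) mr$centroids else mr
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", centroids$centroid_id,
                   nchar(centroids$sequence)),
           sprintf("@RG\tID:%s\tSM:%s", sort(unique(reads$individual_id)),
                   sort(unique(reads$individual_id))),
           paste0("@PG\tID:gbsnp\tPN:gbsnp\tVN:",
                  as.character(utils::packageVersion("gbsnp"))))
  a <- copy(alignments)
  a[, sequence := reads$sequence]
  mapped <- !is.na(a$centroid_id)
  seqout <- a$sequence
  rc <- mapped & a$strand == "-"
  if (any(rc)) seqout[rc] <- revcomp(seqout[rc])
  flag <- ifelse(mapped, ifelse(!is.na(a$strand) & a$strand == "-", 16L, 0L), 4L)
  lines <- paste(a$read_id, flag,
                 ifelse(mapped, a$centroid_id, "*"),
                 ifelse(mapped, a$pos0 + 1L, 0L),
                 ifelse(mapped, 60L, 0L),
                 ifelse(mapped, a$cigar, "*"),
                 "*", 0L, 0L,
                 seqout,
                 vapply(nchar(seqout), function(n) strrep(quality_char, n),
                        character(1)),
                 paste0("RG:Z:", a$individual_id),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

run_config_template <- function() {
  list(
    seed = 1L,
    out_dir = "gbsnp_run",
    log_level = "info",
    sim.n_fragments = 4000L, sim.fragment_length_min = 240L,
    sim.fragment_length_max = 400L, sim.n_snps = 1000L, sim.n_indels = 400L,
    sim.max_indel_len = 10L, sim.n_individuals = 25L, sim.depth_min = 20L,
    sim.depth_max = 30L, sim.error_rate = 0.011, sim.read_length = 150L,
    sim.read_mode = "single", sim.maf_min = 0.1, sim.maf_max = 0.5,
    mockref.individuals = "best", mockref.identity = 0.93,
    mockref.min_count = 2L,
    align.k = 20L, align.band = 12L, align.max_mismatch_frac = 0.1,
    call.min_depth_call = 6L, call.min_minor_depth_het = 3L,
    call.min_minor_frac_het = 0.20, call.max_minor_frac_hom = 0.10,
    call.min_call_rate = 0.75, call.min_alt_carriers = 1L,
    filter.z_threshold = 5, filter.z_method = "pooled",
    ploidy.min_depth = 10L,
    io.write_reads = TRUE, io.write_sam = FALSE, io.gzip = FALSE
  )
}

#' Default pipeline configuration
#'
#' Returns the flat key/value configuration consumed by [run_pipeline()],
#' with any supplied overrides applied. Unknown keys are rejected.
#'
#' @param ... overrides, e.g. `seed = 7`, `sim.n_fragments = 500`.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_template()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (k in names(ov)) {
      cfg[[k]] <- if (is.numeric(cfg[[k]]) && is.integer(cfg[[k]]))
        as.integer(ov[[k]])
      else if (is.numeric(cfg[[k]])) as.numeric(ov[[k]])
      else if (is.logical(cfg[[k]])) as.logical(ov[[k]])
      else as.character(ov[[k]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration file
#'
#' The on-disk format is flat `key = value` text, one key per line; it
#' round-trips losslessly and unknown keys are rejected on read.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` / the parsed `run_config`.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(unclass(config)), function(k)
    sprintf("%s = %s", k, as.character(config[[k]])), character(1))
  writeLines(c("# gbsnp run configuration", lines), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- lines[!grepl("=", lines, fixed = TRUE)]
  if (length(bad))
    stop("malformed config line: ", bad[1], call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (any(!nzchar(keys)))
    stop("malformed config line: ", lines[!nzchar(keys)][1], call. = FALSE)
  do.call(run_config, as.list(setNames(vals, keys)))
}
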