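# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Deterministic per-stage sub-seeds fanned out from one integer seed.
# Stage labels keep the streams independent and reproducible; the arithmetic
# stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(fragments = 1L, variants = 2L, genotypes = 3L, reads = 4L,
              mockref = 5L, align = 6L, call = 7L, ploidy = 8L, eval = 9L)
  off <- stages[[stage]]
  (abs(as.integer(seed)) %% 599999L) * 3001L + off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

fmt_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"), seq_len(n))
}

# Walk a CIGAR string; returns data.table(op, len)
parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.table(op = ops, len = lens)
}

# Project a 0-based query position onto the reference through an alignment
# (ref_start, cigar). Positions inside query-only segments (I/S) project to
# the anchoring reference base; returns NA when the position is soft-clipped
# at the end with no anchor.
project_through_cigar <- function(cigar, ref_start, qpos) {
  cg <- parse_cigar(cigar)
  q <- 0L
  r <- ref_start
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]
    len <- cg$len[i]
    if (op == "M") {
      if (qpos < q + len) return(r + (qpos - q))
      q <- q + len
      r <- r + len
    } else if (op == "I" || op == "S") {
      if (qpos < q + len) return(if (r > ref_start) r - 1L else NA_integer_)
      q <- q + len
    } else if (op == "D") {
      r <- r + len
    }
  }
  NA_integer_
}
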