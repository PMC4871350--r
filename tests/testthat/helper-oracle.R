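# Independent brute-force re-implementation of screen counting, used as the
# oracle for the extraction/translation pipeline. Deliberately different
# machinery from the package: sliding-window substring scan instead of
# regexpr, seqinr's codon translation instead of Biostrings' table, per-read
# loops instead of vectorized passes.

oracle_extract_one <- function(read, flank5, flank3, ilen) {
  f5len <- nchar(flank5)
  f3len <- nchar(flank3)
  n <- nchar(read)
  if (n < f5len + ilen + f3len) return(NA_character_)
  starts <- seq_len(n - f3len + 1L)
  hits <- starts[substring(read, starts, starts + f3len - 1L) == flank3]
  for (h in hits) {
    if (h >= ilen + f5len + 1L &&
        substring(read, h - ilen - f5len, h - ilen - 1L) == flank5) {
      return(substring(read, h - ilen, h - 1L))
    }
  }
  NA_character_
}

oracle_nnk_valid <- function(insert) {
  third <- substring(insert, seq(3L, nchar(insert), 3L),
                     seq(3L, nchar(insert), 3L))
  all(third %in% c("G", "T"))
}

oracle_translate <- function(insert, amber_as_gln = TRUE) {
  aa <- seqinr::translate(strsplit(insert, "")[[1L]])
  if (amber_as_gln) {
    codons <- substring(insert, seq(1L, nchar(insert), 3L),
                        seq(3L, nchar(insert), 3L))
    aa[codons == "TAG"] <- "Q"
  }
  if (any(aa == "*")) return(NA_character_)
  paste(aa, collapse = "")
}

# Full brute-force recount of a FASTQ, mirroring the documented rejection
# precedence: no_flank > ambiguous_base > codon_constraint > stop.
oracle_count_fastq <- function(path, scheme) {
  lines <- readLines(path, warn = FALSE)
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  stats <- c(total_reads = length(seqs), accepted_reads = 0L,
             rejected_no_flank = 0L, rejected_ambiguous_base = 0L,
             rejected_codon_constraint = 0L, rejected_stop = 0L)
  counts <- new.env(parent = emptyenv())
  for (read in seqs) {
    insert <- oracle_extract_one(read, scheme$flank5, scheme$flank3,
                                 scheme$insert_length)
    if (is.na(insert)) {
      stats["rejected_no_flank"] <- stats["rejected_no_flank"] + 1L
    } else if (grepl("[^ACGT]", insert)) {
      stats["rejected_ambiguous_base"] <- stats["rejected_ambiguous_base"] + 1L
    } else if (scheme$codon_filter && !oracle_nnk_valid(insert)) {
      stats["rejected_codon_constraint"] <- stats["rejected_codon_constraint"] + 1L
    } else {
      pep <- oracle_translate(insert, scheme$amber_as_gln)
      if (is.na(pep)) {
        stats["rejected_stop"] <- stats["rejected_stop"] + 1L
      } else {
        stats["accepted_reads"] <- stats["accepted_reads"] + 1L
        counts[[pep]] <- (if (is.null(counts[[pep]])) 0L else counts[[pep]]) + 1L
      }
    }
  }
  peps <- ls(counts)
  out_stats <- as.list(stats)
  out_stats$unique_peptides <- length(peps)
  list(counts = stats::setNames(vapply(peps, function(p) counts[[p]],
                                       integer(1L)), peps),
       stats = out_stats)
}
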