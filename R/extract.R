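#' Construct a per-screen peptide count table
#'
#' The unit of part-one output: one biopanning screen's peptide counts plus
#' full read accounting. [process_screen()] builds these from FASTQ; this
#' constructor exists so count-level data (e.g. previously extracted screens,
#' or designed test libraries) can enter the part-two analysis directly.
#'
#' The read accounting is an exact partition:
#' `total_reads == accepted + no_flank + ambiguous_base + codon_constraint + stop`.
#' When constructed from counts alone, reads beyond `sum(counts)` are booked
#' as flank failures.
#'
#' @param screen_id Label for the screen (e.g. `"(+) CAF 1"`).
#' @param counts Named integer vector, peptide -> read count (all > 0,
#'   unique names).
#' @param total_reads Total reads in the screen's FASTQ; defaults to
#'   `sum(counts)`. Normalization divides by this, not by accepted reads.
#' @param scheme_name Label of the library scheme the peptides came from.
#' @param stats Optional full accounting list; computed if omitted.
#' @return An object of class `screen_table`.
#' @export
screen_table <- function(screen_id, counts, total_reads = sum(counts),
                         scheme_name = "custom", stats = NULL) {
  counts <- unlist(counts)
  if (length(counts) && (is.null(names(counts)) || anyDuplicated(names(counts)))) {
    stop("counts must be uniquely named by peptide", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (any(counts <= 0L)) {
    stop("counts must be positive integers", call. = FALSE)
  }
  accepted <- sum(counts)
  total_reads <- as.integer(total_reads)
  if (total_reads < accepted) {
    stop("total_reads (", total_reads, ") < accepted reads (", accepted, ")",
         call. = FALSE)
  }
  if (is.null(stats)) {
    stats <- list(total_reads = total_reads, accepted_reads = accepted,
                  rejected_no_flank = total_reads - accepted,
                  rejected_ambiguous_base = 0L,
                  rejected_codon_constraint = 0L, rejected_stop = 0L,
                  unique_peptides = length(counts))
  }
  obj <- structure(list(screen_id = screen_id, scheme_name = scheme_name,
                        counts = counts, stats = stats),
                   class = "screen_table")
  validate_screen_table(obj)
  obj
}

validate_screen_table <- function(x) {
  s <- x$stats
  parts <- s$rejected_no_flank + s$rejected_ambiguous_base +
    s$rejected_codon_constraint + s$rejected_stop
  stopifnot(
    s$accepted_reads == sum(x$counts),
    s$total_reads == s$accepted_reads + parts,
    s$unique_peptides == length(x$counts)
  )
  invisible(x)
}

#' @export
print.screen_table <- function(x, ...) {
  s <- x$stats
  cat("Screen '", x$screen_id, "' (scheme ", x$scheme_name, ")\n", sep = "")
  cat(sprintf("  total %d | accepted %d | unique peptides %d\n",
              s$total_reads, s$accepted_reads, s$unique_peptides))
  cat(sprintf("  rejected: no flank %d, ambiguous base %d, codon %d, stop %d\n",
              s$rejected_no_flank, s$rejected_ambiguous_base,
              s$rejected_codon_constraint, s$rejected_stop))
  invisible(x)
}

# Read a 4-line-record FASTQ (plain or gzip); returns the sequence lines,
# uppercased. Malformed records are reported by index.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(character(0L))
  if (n %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': truncated record ", n %/% 4L + 1L,
         call. = FALSE)
  }
  heads <- lines[seq(1L, n, by = 4L)]
  plus  <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " lacks '@'/'+' markers", call. = FALSE)
  }
  toupper(lines[seq(2L, n, by = 4L)])
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorized insert localization. For each read, find the leftmost flank3
# occurrence that (a) leaves room for insert + flank5 before it and (b) is
# immediately preceded, across the insert, by flank5. Returns the candidate
# insert or NA (no qualifying flank pair).
locate_inserts <- function(seqs, scheme) {
  ilen <- scheme$insert_length
  f5 <- scheme$flank5
  f5len <- nchar(f5)
  minstart <- ilen + f5len + 1L
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  active <- seq_len(n)
  offset <- integer(n)
  cur <- seqs
  while (length(active)) {
    m <- regexpr(scheme$flank3, cur, fixed = TRUE)
    found <- m > 0L
    hit <- active[found]
    if (length(hit)) {
      abs_pos <- offset[hit] + m[found]
      ok <- abs_pos >= minstart &
        substr(seqs[hit], abs_pos - ilen - f5len, abs_pos - ilen - 1L) == f5
      pos[hit[ok]] <- abs_pos[ok]
      retry <- hit[!ok]
      offset[retry] <- abs_pos[!ok]
      active <- retry
      cur <- substr(seqs[retry], offset[retry] + 1L, nchar(seqs[retry]))
    } else {
      active <- integer(0L)
    }
  }
  ifelse(is.na(pos), NA_character_, substr(seqs, pos - ilen, pos - 1L))
}

#' Extract the randomized insert from one read
#'
#' Searches the read for the library's 3' flanking signature (the longer,
#' more specific anchor), takes the `insert_length` nucleotides immediately
#' before it as the candidate insert, and accepts only if the 5' signature
#' sits immediately before the insert. The leftmost flank pair satisfying
#' both conditions wins. Rejections are returned as values, not errors:
#' `"no_flank"` when no qualifying pair exists (including reads too short to
#' hold one), `"ambiguous_base"` when the insert contains a non-A/C/G/T
#' character such as N.
#'
#' @param read_sequence One read (may contain N).
#' @param scheme A [make_scheme()] object.
#' @return A list with `insert` (DNA or `NA`) and `rejection` (`NA`,
#'   `"no_flank"` or `"ambiguous_base"`).
#' @examples
#' phd7 <- make_scheme("NEB-PhD7")
#' extract_insert(paste0("AAATCT", "CATACGACGATTCCGAAGGTT", "GGAGGTGGACCC"),
#'                phd7)
#' @export
extract_insert <- function(read_sequence, scheme) {
  stopifnot(nchar(read_sequence) > 0L)
  insert <- locate_inserts(toupper(read_sequence), scheme)
  if (is.na(insert)) {
    list(insert = NA_character_, rejection = "no_flank")
  } else if (grepl("[^ACGT]", insert)) {
    list(insert = NA_character_, rejection = "ambiguous_base")
  } else {
    list(insert = insert, rejection = NA_character_)
  }
}

#' Process one demultiplexed FASTQ screen into a peptide count table
#'
#' Part one of the analysis for a single screen: every read is searched for
#' the flank pair, the insert is checked against the codon constraint,
#' translated, and accepted peptides are tallied. Quality scores are ignored
#' throughout — no quality filtering is applied. The returned accounting
#' partitions every read into exactly one of: accepted, no qualifying flank,
#' ambiguous base in insert, codon outside the library design, or stop codon.
#'
#' @param fastq_path Path to a FASTQ file (plain or gzip), 4-line records.
#' @param scheme A [make_scheme()] object.
#' @param screen_id Label for the screen.
#' @param try_revcomp Retry reads that fail flank search on their reverse
#'   complement. Off by default: amplicon reads are oriented by the
#'   sequencing primer.
#' @return A [screen_table()].
#' @export
process_screen <- function(fastq_path, scheme, screen_id = basename(fastq_path),
                           try_revcomp = FALSE) {
  seqs <- read_fastq_sequences(fastq_path)
  n <- length(seqs)
  if (n == 0L) {
    warning("FASTQ '", fastq_path, "' contains no reads; returning an empty ",
            "screen table", call. = FALSE)
  }
  inserts <- locate_inserts(seqs, scheme)
  if (try_revcomp && anyNA(inserts)) {
    miss <- which(is.na(inserts))
    inserts[miss] <- locate_inserts(reverse_complement(seqs[miss]), scheme)
  }
  no_flank <- is.na(inserts)
  cand <- inserts[!no_flank]
  ambiguous <- grepl("[^ACGT]", cand)
  clean <- cand[!ambiguous]
  codon_ok <- inserts_codon_valid(clean, scheme)
  peptides <- translate_inserts(clean[codon_ok], scheme)
  stopped <- is.na(peptides)
  kept <- peptides[!stopped]
  counts <- sort(table(kept), decreasing = TRUE)
  counts_int <- as.integer(counts)
  names(counts_int) <- names(counts)
  stats <- list(
    total_reads = n,
    accepted_reads = length(kept),
    rejected_no_flank = sum(no_flank),
    rejected_ambiguous_base = sum(ambiguous),
    rejected_codon_constraint = sum(!codon_ok),
    rejected_stop = sum(stopped),
    unique_peptides = length(counts_int)
  )
  screen_table(screen_id, counts_int, total_reads = n,
               scheme_name = scheme$name, stats = stats)
}

#' Write / read a screen count table
#'
#' Screens are stored as plain CSV with columns `peptide,count`, preceded by
#' `#`-commented header lines carrying the screen id, scheme name and the
#' full read accounting, so that a round trip reproduces the table exactly,
#' stats included.
#'
#' @param table A [screen_table()].
#' @param path Output CSV path.
#' @return `write_screen_table` returns `path` invisibly; `read_screen_table`
#'   returns the reconstructed [screen_table()].
#' @export
write_screen_table <- function(table, path) {
  validate_screen_table(table)
  s <- table$stats
  header <- c(
    paste0("# screen_id: ", table$screen_id),
    paste0("# scheme: ", table$scheme_name),
    paste0("# total_reads: ", s$total_reads),
    paste0("# accepted_reads: ", s$accepted_reads),
    paste0("# rejected_no_flank: ", s$rejected_no_flank),
    paste0("# rejected_ambiguous_base: ", s$rejected_ambiguous_base),
    paste0("# rejected_codon_constraint: ", s$rejected_codon_constraint),
    paste0("# rejected_stop: ", s$rejected_stop),
    "peptide,count"
  )
  body <- paste(names(table$counts), table$counts, sep = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("screen table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  rest <- lines[!startsWith(lines, "#")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (length(rest) == 0L || rest[1L] != "peptide,count") {
    stop("input-format error in '", path,
         "': expected header 'peptide,count'", call. = FALSE)
  }
  body <- rest[-1L]
  body <- body[nzchar(body)]
  if (length(body)) {
    fields <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(fields) != 2L)) {
      stop("input-format error in '", path, "': malformed row", call. = FALSE)
    }
    peptide <- vapply(fields, `[[`, character(1L), 1L)
    count <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
    if (anyNA(count) || any(count <= 0L)) {
      stop("input-format error in '", path,
           "': counts must be positive integers", call. = FALSE)
    }
    if (anyDuplicated(peptide)) {
      stop("input-format error in '", path, "': duplicate peptide '",
           peptide[anyDuplicated(peptide)], "'", call. = FALSE)
    }
    counts <- stats::setNames(count, peptide)
  } else {
    counts <- stats::setNames(integer(0L), character(0L))
  }
  num <- function(key) {
    v <- suppressWarnings(as.integer(meta[[key]]))
    if (is.null(meta[[key]]) || is.na(v)) {
      stop("input-format error in '", path, "': missing stat '", key, "'",
           call. = FALSE)
    }
    v
  }
  stats <- list(total_reads = num("total_reads"),
                accepted_reads = num("accepted_reads"),
                rejected_no_flank = num("rejected_no_flank"),
                rejected_ambiguous_base = num("rejected_ambiguous_base"),
                rejected_codon_constraint = num("rejected_codon_constraint"),
                rejected_stop = num("rejected_stop"),
                unique_peptides = length(counts))
  screen_table(meta[["screen_id"]], counts,
               total_reads = stats$total_reads,
               scheme_name = meta[["scheme"]], stats = stats)
}
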