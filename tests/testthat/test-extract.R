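phd7 <- make_scheme("NEB-PhD7")
INSERT <- "CATACGACGATTCCGAAGGTT"  # HTTIPKV

fastq_of <- function(seqs, path = withr::local_tempfile(fileext = ".fastq",
                                                        .local_envir = parent.frame())) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

test_that("extract_insert finds the flank pair and reports rejections as values", {
  ok <- extract_insert(paste0("AAA", "TCT", INSERT, "GGAGGTGGA", "CCC"), phd7)
  expect_equal(ok$insert, INSERT)
  expect_true(is.na(ok$rejection))

  no5 <- extract_insert(paste0("AAAA", INSERT, "GGAGGTGGA"), phd7)
  expect_equal(no5$rejection, "no_flank")

  amb <- extract_insert(paste0("AAA", "TCT", sub("A", "N", INSERT),
                               "GGAGGTGGA"), phd7)
  expect_equal(amb$rejection, "ambiguous_base")

  # leftmost *qualifying* flank3 wins: a decoy flank3 with no insert room
  # before it must be skipped
  decoy <- extract_insert(paste0("GGAGGTGGA", "TT", "TCT", INSERT,
                                 "GGAGGTGGA"), phd7)
  expect_equal(decoy$insert, INSERT)

  expect_equal(extract_insert("ACGT", phd7)$rejection, "no_flank")
})

test_that("process_screen counts peptides with exact read accounting", {
  good <- paste0("ACGT", "TCT", INSERT, "GGAGGTGGA", "AC")
  noflank <- paste0("ACGT", INSERT, "GGAGGTGGA")
  badcodon <- paste0("TCT", sub("^CAT", "CAA", INSERT), "GGAGGTGGA")
  fq <- fastq_of(c(good, good, noflank, badcodon))
  tab <- process_screen(fq, phd7, "toy")
  expect_equal(unname(tab$counts["HTTIPKV"]), 2L)
  expect_equal(tab$stats$total_reads, 4L)
  expect_equal(tab$stats$accepted_reads, 2L)
  expect_equal(tab$stats$rejected_no_flank, 1L)
  expect_equal(tab$stats$rejected_codon_constraint, 1L)
  expect_equal(tab$stats$unique_peptides, 1L)
})

test_that("the five-way stats partition holds on adversarial fixtures", {
  for (seed in c(3L, 17L)) {
    fq <- withr::local_tempfile(fileext = ".fastq")
    make_fixture_fastq(fq, seed, n_reads = 300L)
    tab <- process_screen(fq, phd7, "fix")
    s <- tab$stats
    expect_equal(s$total_reads,
                 s$accepted_reads + s$rejected_no_flank +
                   s$rejected_ambiguous_base + s$rejected_codon_constraint +
                   s$rejected_stop)
    expect_equal(sum(tab$counts), s$accepted_reads)
    expect_equal(s$rejected_stop, 0L)  # NNK filter precludes stop rejections
  }
})

test_that("shuffling reads leaves the screen table unchanged", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  make_fixture_fastq(fq, 23L, n_reads = 200L)
  lines <- readLines(fq)
  rec <- split(lines, rep(seq_len(length(lines) / 4L), each = 4L))
  set.seed(1)
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(unlist(rec[sample.int(length(rec))]), fq2)
  t1 <- process_screen(fq, phd7, "a")
  t2 <- process_screen(fq2, phd7, "a")
  expect_equal(sort(t1$counts), sort(t2$counts))
  expect_equal(t1$stats, t2$stats)
})

test_that("reverse-complement retry recovers flipped reads when enabled", {
  fwd <- paste0("ACGT", "TCT", INSERT, "GGAGGTGGA", "AC")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  fq <- fastq_of(c(fwd, rc))
  expect_equal(process_screen(fq, phd7, "x")$stats$accepted_reads, 1L)
  tab <- process_screen(fq, phd7, "x", try_revcomp = TRUE)
  expect_equal(unname(tab$counts["HTTIPKV"]), 2L)
})

test_that("empty and malformed FASTQ inputs are handled per contract", {
  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  expect_warning(tab <- process_screen(empty, phd7, "empty"), "no reads")
  expect_equal(tab$stats$total_reads, 0L)
  expect_equal(length(tab$counts), 0L)

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(process_screen(trunc, phd7, "t"), "record 2")

  junk <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("r1", "ACGT", "+", "IIII"), junk)
  expect_error(process_screen(junk, phd7, "j"), "record 1")
})

test_that("gzipped FASTQ is read transparently", {
  good <- paste0("TCT", INSERT, "GGAGGTGGA")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "w")
  writeLines(c("@r1", good, "+", strrep("I", nchar(good))), con)
  close(con)
  expect_equal(unname(process_screen(gz, phd7, "gz")$counts["HTTIPKV"]), 1L)
})

test_that("screen tables round-trip through CSV including stats", {
  tab <- screen_table("demo", c(HTTIPKV = 2L, APPIMSV = 1L),
                      total_reads = 10L, scheme_name = "NEB-PhD7")
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(tab, path)
  back <- read_screen_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$stats, tab$stats)
  expect_equal(back$screen_id, "demo")
  expect_equal(back$scheme_name, "NEB-PhD7")
})

test_that("corrupt screen tables are rejected on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- screen_table("demo", c(HTTIPKV = 2L), total_reads = 5L)
  write_screen_table(tab, path)
  lines <- readLines(path)

  neg <- sub("HTTIPKV,2", "HTTIPKV,-3", lines)
  writeLines(neg, path)
  expect_error(read_screen_table(path), "positive integers")

  dup <- c(lines, "HTTIPKV,4")
  writeLines(dup, path)
  expect_error(read_screen_table(path), "duplicate")

  writeLines(lines[!startsWith(lines, "peptide")][1:3], path)
  expect_error(read_screen_table(path), "input-format")
})
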