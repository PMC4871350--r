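# Adversarial fixture FASTQ generator, independent of the package's
# simulator. Mixes clean reads with flank-less reads, N-contaminated
# inserts, codon-constraint violations, stop-codon inserts, decoy flank
# occurrences and truncated reads, with random padding so nothing sits at a
# fixed offset.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_nnk_insert <- function(k = 7L) {
  paste(vapply(seq_len(k), function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                 collapse = ""),
           sample(c("G", "T"), 1L))
  }, character(1L)), collapse = "")
}

make_fixture_fastq <- function(path, seed, n_reads = 500L,
                               scheme = make_scheme("NEB-PhD7")) {
  set.seed(seed)
  k <- scheme$peptide_length
  reads <- vapply(seq_len(n_reads), function(i) {
    kind <- sample(c("clean", "no_flank", "ambig", "bad_codon", "stop",
                     "decoy", "short"), 1L,
                   prob = c(0.55, 0.1, 0.08, 0.1, 0.05, 0.07, 0.05))
    pad5 <- rand_dna(sample(0:12, 1L))
    pad3 <- rand_dna(sample(0:12, 1L))
    core <- switch(kind,
      clean = paste0(scheme$flank5, rand_nnk_insert(k), scheme$flank3),
      no_flank = rand_dna(nchar(scheme$flank5) + 3L * k +
                            nchar(scheme$flank3)),
      ambig = {
        ins <- rand_nnk_insert(k)
        substr(ins, sample(nchar(ins), 1L), sample(nchar(ins), 1L)) <- "N"
        paste0(scheme$flank5, ins, scheme$flank3)
      },
      bad_codon = {
        ins <- rand_nnk_insert(k)
        pos <- 3L * sample(k, 1L)
        substr(ins, pos, pos) <- sample(c("A", "C"), 1L)
        paste0(scheme$flank5, ins, scheme$flank3)
      },
      stop = {
        ins <- rand_nnk_insert(k)
        substr(ins, 1L, 3L) <- sample(c("TAA", "TGA"), 1L)
        paste0(scheme$flank5, ins, scheme$flank3)
      },
      decoy = paste0(scheme$flank3, rand_dna(2L), scheme$flank5,
                     rand_nnk_insert(k), scheme$flank3),
      short = rand_dna(sample(5:15, 1L))
    )
    paste0(pad5, core, pad3)
  }, character(1L))
  out <- character(4L * n_reads)
  out[seq(1L, length(out), 4L)] <- paste0("@fix_", seq_len(n_reads))
  out[seq(2L, length(out), 4L)] <- reads
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- strrep("E", nchar(reads))
  writeLines(out, path)
  invisible(path)
}

# Small normalized-screen builder for selection-logic tests.
ns_from_counts <- function(id, counts, total, ref_counts, ref_total) {
  ref_dn <- ref_counts / ref_total
  reference_normalize(counts / total, ref_dn, nonzero_mode(ref_dn),
                      screen_id = id, total_reads = total)
}

# Simulated screen set for end-to-end tests: one reference + n_pos positives
# + n_neg negatives from a shared pool, parasites amplified everywhere,
# spikes only in positives. Returns the processed screen tables.
simulate_screen_set <- function(pool, spikes, parasites, scheme, n_reads,
                                error_rate, seed, n_pos = 3L, n_neg = 3L,
                                dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ids <- c("REF", paste0("POS", seq_len(n_pos)), paste0("NEG", seq_len(n_neg)))
  tables <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    sel <- if (startsWith(id, "POS")) spikes else numeric()
    spec <- screen_sim_spec(n_reads, pool, selective_spikes = sel,
                            parasitic_clones = parasites,
                            error_rate = error_rate, scheme = scheme,
                            seed = seed * 100L + i)
    fq <- file.path(dir, paste0(id, ".fastq"))
    simulate_screen(spec, fq, truth_path = NULL)
    tables[[id]] <- process_screen(fq, scheme, id)
  }
  tables
}
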