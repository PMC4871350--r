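#' End-to-end spiked-recovery benchmark
#'
#' Simulates one complete selectivity study and measures whether the analysis
#' recovers the planted truth: a skewed naive pool is screened in three
#' positive and three negative screens plus an unselected reference, a few
#' clones are made target-selective (enriched in positives only) and a few
#' parasitic (amplified everywhere, reference included), all screens are
#' extracted, normalized and ranked, and the function reports which planted
#' clones reached the top fraction of the comparison matrix. Selective clones
#' should land in the top rows essentially always; parasitic-only clones
#' should not, because the reference normalization cancels amplification
#' bias.
#'
#' The defaults are the package's standard benchmark conditions: 10,000
#' unique clones at log-normal skew 1.5, 100,000 reads per screen, five
#' selective spikes at 50x, five parasitic clones at 20x, substitution error
#' 0.001 per base, top fraction 1%.
#'
#' @param seed Integer seed controlling pool, spike choice, sampling and
#'   errors for this run.
#' @param n_reads Reads per screen.
#' @param n_unique Unique clones in the naive pool.
#' @param skew Log-normal sigma of pool weights.
#' @param n_spikes,spike_factor Number and fold-enrichment of selective
#'   clones (positives only).
#' @param n_parasites,parasite_factor Number and fold-amplification of
#'   parasitic clones (every screen, reference included).
#' @param error_rate Per-base substitution error rate.
#' @param n_pos,n_neg Number of positive / negative screens.
#' @param top_frac Top fraction of matrix rows counted as "recovered".
#' @param dir Working directory for the intermediate FASTQ files.
#' @return List: `selective_recovered` / `n_selective`, `parasitic_in_top`
#'   (parasitic-only clones found in the top fraction), `top_n`, `n_rows`,
#'   `selective_peptides`, `parasitic_peptides`, and the sorted `matrix`.
#' @export
spiked_recovery_run <- function(seed, n_reads = 100000L, n_unique = 10000L,
                                skew = 1.5, n_spikes = 5L, spike_factor = 50,
                                n_parasites = 5L, parasite_factor = 20,
                                error_rate = 0.001, n_pos = 3L, n_neg = 3L,
                                top_frac = 0.01, dir = tempfile("spike_run")) {
  scheme <- make_scheme("NEB-PhD7")
  pool <- generate_naive_pool(n_unique, skew, scheme, seed = seed)
  set.seed(seed + 500000L)
  idx <- sample.int(length(pool), n_spikes + n_parasites)
  spikes <- stats::setNames(rep(spike_factor, n_spikes),
                            names(pool)[idx[seq_len(n_spikes)]])
  parasites <- stats::setNames(rep(parasite_factor, n_parasites),
                               names(pool)[idx[-seq_len(n_spikes)]])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ids <- c("REF", paste0("POS", seq_len(n_pos)), paste0("NEG", seq_len(n_neg)))
  tables <- list()
  for (i in seq_along(ids)) {
    spec <- screen_sim_spec(
      n_reads, pool,
      selective_spikes = if (startsWith(ids[i], "POS")) spikes else numeric(),
      parasitic_clones = parasites,
      error_rate = error_rate, scheme = scheme, seed = seed * 1000L + i)
    fq <- file.path(dir, paste0(ids[i], ".fastq"))
    simulate_screen(spec, fq, truth_path = NULL)
    tables[[ids[i]]] <- process_screen(fq, scheme, ids[i])
  }
  assignment <- role_assignment("REF", ids[startsWith(ids, "POS")],
                                ids[startsWith(ids, "NEG")])
  matrix <- build_matrix(normalize_screens(tables, assignment), assignment)
  top_n <- ceiling(top_frac * nrow(matrix$values))
  top <- rownames(matrix$values)[seq_len(top_n)]
  selective_peptides <- unique(translate_inserts(names(spikes), scheme))
  parasitic_peptides <- setdiff(unique(translate_inserts(names(parasites),
                                                         scheme)),
                                selective_peptides)
  list(selective_recovered = sum(selective_peptides %in% top),
       n_selective = length(selective_peptides),
       parasitic_in_top = sum(parasitic_peptides %in% top),
       top_n = top_n, n_rows = nrow(matrix$values),
       selective_peptides = selective_peptides,
       parasitic_peptides = parasitic_peptides,
       matrix = matrix)
}
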