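#' Generate a skewed naive phage pool
#'
#' Commercial display libraries are far from uniform: clone abundances in the
#' naive pool span orders of magnitude. The generator draws `n_unique`
#' distinct codon-valid inserts for the scheme and assigns them log-normal
#' abundance weights with the given shape parameter `skew` (sigma of the
#' log-normal; `skew = 0` gives an equal-abundance pool). Deterministic for a
#' fixed seed.
#'
#' @param n_unique Number of distinct clones (must not exceed the codon space
#'   of the scheme, e.g. `32^7` for an NNK 7-mer).
#' @param skew Log-normal sigma of the abundance weights; 1.5 is a realistic
#'   default for an amplified naive library.
#' @param scheme A [make_scheme()] object.
#' @param seed Integer RNG seed.
#' @return Named numeric vector: insert DNA -> positive weight.
#' @export
generate_naive_pool <- function(n_unique, skew = 1.5,
                                scheme = make_scheme("NEB-PhD7"), seed = 1L) {
  n_unique <- as.integer(n_unique)
  stopifnot(n_unique >= 1L, skew >= 0)
  space <- n_codons_allowed(scheme)^scheme$peptide_length
  if (n_unique > space) {
    stop("n_unique (", n_unique, ") exceeds the codon-valid sequence space (",
         format(space, big.mark = ","), ")", call. = FALSE)
  }
  set.seed(seed)
  inserts <- character(0L)
  while (length(inserts) < n_unique) {
    need <- n_unique - length(inserts)
    inserts <- unique(c(inserts, random_inserts(ceiling(need * 1.1) + 10L,
                                                scheme)))
  }
  inserts <- inserts[seq_len(n_unique)]
  weights <- stats::rlnorm(n_unique, meanlog = 0, sdlog = skew)
  stats::setNames(weights, inserts)
}

# Codons a viable library member may carry under the scheme: they must match
# the constraint pattern and must not terminate translation (TAG survives
# under amber read-through).
viable_codons <- function(scheme) {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  tab <- codon_table(scheme$amber_as_gln)
  ok <- tab[all64] != "*"
  if (!identical(scheme$codon_constraint, "unconstrained")) {
    sets <- constraint_sets(scheme$codon_constraint)
    for (p in 1:3) ok <- ok & substr(all64, p, p) %in% sets[[p]]
  }
  all64[ok]
}

n_codons_allowed <- function(scheme) length(viable_codons(scheme))

# Draw n random viable inserts (not necessarily distinct).
random_inserts <- function(n, scheme) {
  codons <- viable_codons(scheme)
  cols <- vector("list", scheme$peptide_length)
  for (j in seq_len(scheme$peptide_length)) {
    cols[[j]] <- sample(codons, n, replace = TRUE)
  }
  do.call(paste0, cols)
}

#' Specify one synthetic screen
#'
#' Bundles everything needed to emit a simulated FASTQ: the naive pool, the
#' per-clone selection and amplification multipliers, the read budget, the
#' sequencing error rate and the library scheme. Reads are sampled with
#' probability proportional to `weight * enrichment * amplification`, so a
#' selective spike models target-driven selection (apply it in positive
#' screens only) while a parasitic factor models fast bacterial amplification
#' (apply it in every amplified library, the reference included — that is
#' precisely why reference normalization cancels it).
#'
#' @param n_reads Reads to emit.
#' @param naive_pool Named weight vector from [generate_naive_pool()].
#' @param selective_spikes Named numeric (insert -> factor >= 1), target
#'   enrichment.
#' @param parasitic_clones Named numeric (insert -> factor >= 1),
#'   amplification bias.
#' @param error_rate Per-base substitution probability, in [0, 0.1]. Indels
#'   are not modelled.
#' @param scheme A [make_scheme()] object.
#' @param seed Integer RNG seed.
#' @return An object of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_reads, naive_pool, selective_spikes = numeric(),
                            parasitic_clones = numeric(), error_rate = 0.001,
                            scheme = make_scheme("NEB-PhD7"), seed = 1L) {
  stopifnot(n_reads >= 1L, length(naive_pool) >= 1L, all(naive_pool > 0),
            error_rate >= 0, error_rate <= 0.1)
  for (fac in list(selective_spikes, parasitic_clones)) {
    if (length(fac)) {
      stopifnot(!is.null(names(fac)), all(fac >= 1),
                all(names(fac) %in% names(naive_pool)))
    }
  }
  structure(list(n_reads = as.integer(n_reads), naive_pool = naive_pool,
                 selective_spikes = selective_spikes,
                 parasitic_clones = parasitic_clones,
                 error_rate = error_rate, scheme = scheme,
                 seed = as.integer(seed)),
            class = "screen_sim_spec")
}

# Expected sampling probability per pool member under a spec.
sim_probabilities <- function(spec) {
  w <- spec$naive_pool
  if (length(spec$selective_spikes)) {
    idx <- match(names(spec$selective_spikes), names(w))
    w[idx] <- w[idx] * spec$selective_spikes
  }
  if (length(spec$parasitic_clones)) {
    idx <- match(names(spec$parasitic_clones), names(w))
    w[idx] <- w[idx] * spec$parasitic_clones
  }
  w / sum(w)
}

#' Simulate one screen's FASTQ file
#'
#' Samples reads from the spec's biased pool and writes a 4-line-record
#' FASTQ. Each read embeds `flank5 + insert + flank3` inside fixed
#' primer-like padding, so downstream extraction must genuinely locate the
#' flanks rather than slice fixed offsets. Substitution errors are applied
#' uniformly over the whole read at `error_rate` per base; quality lines are
#' constant (the analysis ignores them). A ground-truth TSV (true abundance,
#' spike and parasite factors, sampled read counts per clone) is written next
#' to the FASTQ.
#'
#' @param spec A [screen_sim_spec()].
#' @param path Output FASTQ path (gzip if it ends in `.gz`).
#' @param truth_path Ground-truth TSV path; default derives from `path`;
#'   `NULL` skips it.
#' @return `path` invisibly, with the ground-truth data frame attached as
#'   attribute `"truth"`.
#' @export
simulate_screen <- function(spec, path,
                            truth_path = paste0(sub("\\.fastq(\\.gz)?$", "",
                                                    path), ".truth.tsv")) {
  set.seed(spec$seed)
  prob <- sim_probabilities(spec)
  counts <- as.integer(stats::rmultinom(1L, spec$n_reads, prob))
  inserts <- rep(names(prob), counts)
  inserts <- inserts[sample.int(length(inserts))]
  sc <- spec$scheme
  # Primer-like constant context flanking the biological signal in the read.
  pre <- "GTACCTTTCTATTCACAC"
  post <- "TTCGGCCGAACCTCCACC"
  reads <- paste0(pre, sc$flank5, inserts, sc$flank3, post)
  if (spec$error_rate > 0) {
    reads <- apply_substitutions(reads, spec$error_rate)
  }
  qual <- strrep("I", nchar(reads[1L]))
  out <- character(4L * length(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@sim_", seq_along(reads))
  out[seq(2L, length(out), 4L)] <- reads
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(out, con)
  close(con)
  truth <- data.frame(
    insert = names(prob),
    peptide = translate_inserts(names(prob), sc),
    weight = unname(spec$naive_pool[names(prob)]),
    selective = unname(ifelse(is.na(spec$selective_spikes[names(prob)]), 1,
                              spec$selective_spikes[names(prob)])),
    parasitic = unname(ifelse(is.na(spec$parasitic_clones[names(prob)]), 1,
                              spec$parasitic_clones[names(prob)])),
    expected_share = unname(prob),
    sampled_reads = counts,
    row.names = NULL)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(structure(path, truth = truth))
}

# Uniform per-base substitutions: each base independently replaced, with
# probability `rate`, by one of the three other bases.
apply_substitutions <- function(reads, rate) {
  len <- nchar(reads[1L])
  total <- length(reads) * len
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  slot <- sample.int(total, n_err)  # without replacement: one hit per base
  read_i <- (slot - 1L) %/% len + 1L
  pos <- (slot - 1L) %% len + 1L
  bases <- c("A", "C", "G", "T")
  old <- substring(reads[read_i], pos, pos)
  # replacement = old base shifted by a random 1..3 in the cyclic base order,
  # i.e. uniform over the three other bases
  new <- bases[((match(old, bases) - 1L +
                   sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L]
  for (e in seq_len(n_err)) {
    substr(reads[read_i[e]], pos[e], pos[e]) <- new[e]
  }
  reads
}

#' Derive a second-round screen spec from a first-round outcome
#'
#' Two rounds of biopanning compose selection multiplicatively: the pool
#' entering round two is the round-one pool reweighted by the round-one
#' factors, and the round-two factors are applied on top. A clone spiked at
#' `e` per round is therefore enriched `e^2` over the naive pool after two
#' rounds, in expectation.
#'
#' @param spec1 The round-one [screen_sim_spec()].
#' @param selective_spikes,parasitic_clones Round-two factors (default:
#'   repeat round one's).
#' @param seed RNG seed for round two.
#' @return A [screen_sim_spec()] whose naive pool is round one's expected
#'   output distribution.
#' @export
simulate_round2 <- function(spec1, selective_spikes = spec1$selective_spikes,
                            parasitic_clones = spec1$parasitic_clones,
                            seed = spec1$seed + 1L) {
  pool2 <- sim_probabilities(spec1) * sum(spec1$naive_pool)
  screen_sim_spec(spec1$n_reads, pool2,
                  selective_spikes = selective_spikes,
                  parasitic_clones = parasitic_clones,
                  error_rate = spec1$error_rate, scheme = spec1$scheme,
                  seed = seed)
}
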