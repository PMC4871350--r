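#' Define a display-library scheme
#'
#' A library scheme captures the geometry of one phage display library as it
#' appears in an amplicon read: the constant nucleotide signatures flanking
#' the randomized insert, the displayed peptide length, and the degenerate
#' codon design used to synthesize the insert. The scheme drives both insert
#' extraction (where to cut) and translation (which codons are legal and how
#' the amber codon is read).
#'
#' Two presets are built in for the New England Biolabs Ph.D. M13 libraries:
#' `"NEB-PhD7"` (7-mer, 21-nt insert) and `"NEB-PhD12"` (12-mer, 36-nt
#' insert). Both use the flanks `TCT` (5') and `GGAGGTGGA` (3'), NNK codons,
#' and translate the amber stop `TAG` as glutamine, reflecting propagation in
#' a supE amber-suppressor host. Calling `make_scheme("NEB-PhD7")` with no
#' other arguments resolves the preset.
#'
#' @param name Scheme label, or the name of a built-in preset.
#' @param flank5 Constant DNA immediately 5' of the insert (A/C/G/T only).
#' @param flank3 Constant DNA immediately 3' of the insert (A/C/G/T only).
#' @param peptide_length Number of displayed residues (k); the insert spans
#'   `3 * k` nucleotides.
#' @param codon_constraint Per-position degenerate codon pattern as a 3-letter
#'   IUPAC string (e.g. `"NNK"`), or `"unconstrained"` to accept any codon.
#' @param amber_as_gln Translate the amber codon TAG as glutamine (Q) instead
#'   of rejecting the read as a stop. Default `TRUE`: NNK-synthesized NEB
#'   libraries include TAG and are grown in supE hosts.
#' @param codon_filter Reject reads whose insert contains a codon outside the
#'   constraint. Defaults to `TRUE` when a constraint pattern is given,
#'   `FALSE` for unconstrained schemes.
#'
#' @return An object of class `library_scheme` with fields `name`, `flank5`,
#'   `flank3`, `peptide_length`, `insert_length`, `codon_constraint`,
#'   `amber_as_gln`, `codon_filter`.
#'
#' @examples
#' make_scheme("NEB-PhD7")
#' make_scheme("custom", "TCT", "GGAGGTGGA", 12, "NNK", amber_as_gln = TRUE)
#' @export
make_scheme <- function(name, flank5 = NULL, flank3 = NULL,
                        peptide_length = NULL, codon_constraint = "NNK",
                        amber_as_gln = TRUE, codon_filter = NULL) {
  presets <- list(
    "NEB-PhD7"  = list(flank5 = "TCT", flank3 = "GGAGGTGGA",
                       peptide_length = 7L, codon_constraint = "NNK",
                       amber_as_gln = TRUE, codon_filter = TRUE),
    "NEB-PhD12" = list(flank5 = "TCT", flank3 = "GGAGGTGGA",
                       peptide_length = 12L, codon_constraint = "NNK",
                       amber_as_gln = TRUE, codon_filter = TRUE)
  )
  if (name %in% names(presets) && is.null(flank5) && is.null(flank3) &&
      is.null(peptide_length)) {
    p <- presets[[name]]
    return(make_scheme(name, p$flank5, p$flank3, p$peptide_length,
                       p$codon_constraint, p$amber_as_gln, p$codon_filter))
  }
  if (is.null(flank5) || is.null(flank3) || is.null(peptide_length)) {
    stop("invalid scheme: '", name, "' is not a preset, so flank5, flank3 ",
         "and peptide_length must all be given", call. = FALSE)
  }
  flank5 <- toupper(as.character(flank5))
  flank3 <- toupper(as.character(flank3))
  for (fl in list(c("flank5", flank5), c("flank3", flank3))) {
    if (nchar(fl[2L]) == 0L || grepl("[^ACGT]", fl[2L])) {
      stop("invalid scheme: ", fl[1L],
           " must be non-empty DNA over A/C/G/T, got '", fl[2L], "'",
           call. = FALSE)
    }
  }
  peptide_length <- as.integer(peptide_length)
  if (is.na(peptide_length) || peptide_length < 1L) {
    stop("invalid scheme: peptide_length must be a positive integer",
         call. = FALSE)
  }
  unconstrained <- identical(tolower(codon_constraint), "unconstrained")
  if (!unconstrained) {
    codon_constraint <- toupper(codon_constraint)
    if (nchar(codon_constraint) != 3L ||
        !all(strsplit(codon_constraint, "")[[1L]] %in%
             names(Biostrings::IUPAC_CODE_MAP))) {
      stop("invalid scheme: codon_constraint must be a 3-letter IUPAC ",
           "pattern or 'unconstrained'", call. = FALSE)
    }
  } else {
    codon_constraint <- "unconstrained"
  }
  if (is.null(codon_filter)) codon_filter <- !unconstrained
  structure(
    list(name = name, flank5 = flank5, flank3 = flank3,
         peptide_length = peptide_length,
         insert_length = 3L * peptide_length,
         codon_constraint = codon_constraint,
         amber_as_gln = isTRUE(amber_as_gln),
         codon_filter = isTRUE(codon_filter) && !unconstrained),
    class = "library_scheme"
  )
}

#' @export
print.library_scheme <- function(x, ...) {
  cat("Display library scheme '", x$name, "'\n", sep = "")
  cat("  insert: ", x$flank5, "[", x$insert_length, " nt / ",
      x$peptide_length, " aa]", x$flank3, "\n", sep = "")
  cat("  codons: ", x$codon_constraint,
      if (x$codon_filter) " (filtering on)" else " (filtering off)",
      if (x$amber_as_gln) ", TAG read as Q" else "", "\n", sep = "")
  invisible(x)
}

# Expand a 3-letter IUPAC codon pattern into the per-position base sets.
constraint_sets <- function(constraint) {
  lapply(strsplit(constraint, "")[[1L]],
         function(code) strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]])
}

#' Test whether a codon satisfies a degenerate-codon constraint
#'
#' NNK libraries restrict the third codon position to G or T, which keeps all
#' 20 amino acids reachable (TAG standing in for Gln) while excluding the
#' ochre (TAA) and opal (TGA) stops. Reads carrying codons outside the design
#' cannot come from a legitimate library member and are removed upstream.
#'
#' @param codon A 3-nt DNA string (A/C/G/T).
#' @param constraint A 3-letter IUPAC pattern (e.g. `"NNK"`) or
#'   `"unconstrained"`.
#' @return `TRUE` if every codon position matches the pattern.
#' @examples
#' codon_is_allowed("CAT", "NNK")  # TRUE
#' codon_is_allowed("ACA", "NNK")  # FALSE: third base A
#' @export
codon_is_allowed <- function(codon, constraint = "NNK") {
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be 3 nt over A/C/G/T, got '", codon, "'", call. = FALSE)
  }
  if (identical(tolower(constraint), "unconstrained")) return(TRUE)
  sets <- constraint_sets(toupper(constraint))
  bases <- strsplit(codon, "")[[1L]]
  all(vapply(1:3, function(i) bases[i] %in% sets[[i]], logical(1L)))
}

# Codon -> amino acid lookup honouring the scheme's amber rule. Stops that
# remain stops map to "*".
codon_table <- function(amber_as_gln) {
  tab <- Biostrings::GENETIC_CODE
  if (amber_as_gln) tab[["TAG"]] <- "Q"
  tab
}

#' Translate one library insert
#'
#' Standard-genetic-code translation of the randomized insert, codon by
#' codon. Under `amber_as_gln` the amber codon TAG is read through as
#' glutamine; the remaining stops (TAA, TGA — and TAG itself when read-through
#' is off) make the read a stop-rejection, returned as `NA` rather than
#' thrown, so callers can count it in the read accounting. Note that a
#' codon-valid NNK insert can never contain TAA or TGA, so with codon
#' filtering on, stop-rejections never occur.
#'
#' @param insert DNA string of exactly `scheme$insert_length` nt (A/C/G/T).
#' @param scheme A [make_scheme()] object.
#' @return The peptide string, or `NA_character_` for a stop-rejection.
#' @examples
#' phd7 <- make_scheme("NEB-PhD7")
#' translate_insert("CATACGACGATTCCGAAGGTT", phd7)  # "HTTIPKV"
#' @export
translate_insert <- function(insert, scheme) {
  if (nchar(insert) != scheme$insert_length || grepl("[^ACGT]", insert)) {
    stop("insert must be ", scheme$insert_length, " nt over A/C/G/T",
         call. = FALSE)
  }
  translate_inserts(insert, scheme)
}

# Vectorized translation used by the screen processor. Returns NA for inserts
# containing a (non-readthrough) stop codon.
translate_inserts <- function(inserts, scheme) {
  k <- scheme$peptide_length
  tab <- codon_table(scheme$amber_as_gln)
  cols <- vector("list", k)
  stopped <- logical(length(inserts))
  for (j in seq_len(k)) {
    aa <- tab[substr(inserts, 3L * j - 2L, 3L * j)]
    stopped <- stopped | aa == "*"
    cols[[j]] <- aa
  }
  pep <- do.call(paste0, cols)
  pep[stopped] <- NA_character_
  pep
}

# Vectorized codon-constraint check for whole inserts.
inserts_codon_valid <- function(inserts, scheme) {
  if (!scheme$codon_filter) return(rep(TRUE, length(inserts)))
  sets <- constraint_sets(scheme$codon_constraint)
  ok <- rep(TRUE, length(inserts))
  for (j in seq_len(scheme$peptide_length)) {
    base <- 3L * (j - 1L)
    for (pos in 1:3) {
      ok <- ok & substr(inserts, base + pos, base + pos) %in% sets[[pos]]
    }
  }
  ok
}
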