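#' Assign screens to reference / positive / negative roles
#'
#' Selectivity analysis compares many independent screens: positives panned
#' against the target, negatives against counter-targets whose binders must
#' be avoided, and exactly one reference — the amplified, unselected library
#' — whose frequencies capture abundance biases (skewed naive distribution,
#' parasitic fast-amplifiers) unrelated to target affinity.
#'
#' @param reference Screen id of the unselected amplified reference library.
#' @param positives Character vector of positive-screen ids (non-empty unless
#'   `allow_no_positives`).
#' @param negatives Character vector of negative-screen ids (may be empty
#'   only in ubiquitous-binder mode).
#' @param allow_no_positives Internal switch for ubiquitous-binder mode.
#' @return An object of class `role_assignment`.
#' @export
role_assignment <- function(reference, positives, negatives = character(),
                            allow_no_positives = FALSE) {
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  reference <- as.character(reference)
  if (length(reference) != 1L || !nzchar(reference)) {
    stop("configuration error: exactly one reference screen is required",
         call. = FALSE)
  }
  if (!allow_no_positives && length(positives) == 0L) {
    stop("configuration error: at least one positive screen is required",
         call. = FALSE)
  }
  all_ids <- c(reference, positives, negatives)
  if (anyDuplicated(all_ids)) {
    stop("configuration error: screen roles must be disjoint; '",
         all_ids[anyDuplicated(all_ids)], "' appears twice", call. = FALSE)
  }
  structure(list(reference = reference, positives = positives,
                 negatives = negatives),
            class = "role_assignment")
}

#' Depth-normalize a screen
#'
#' Divides each peptide's read count by the screen's total read count (all
#' reads in the FASTQ, not only accepted ones), making screens of different
#' sequencing depth comparable. Within-screen ranking is unchanged.
#'
#' @param table A [screen_table()].
#' @return Named numeric vector, peptide -> frequency per read.
#' @export
depth_normalize <- function(table) {
  total <- table$stats$total_reads
  if (is.null(total) || total == 0L) {
    stop("empty-screen error: '", table$screen_id, "' has zero total reads",
         call. = FALSE)
  }
  table$counts / total
}

#' Non-zero mode of a set of frequencies
#'
#' The most frequently occurring strictly positive value, with multiplicity
#' ties broken toward the smallest tied value. Used both as the imputation
#' value for peptides absent from a screen and as the fallback reference
#' denominator for peptides absent from the reference library — in real
#' screens the mode is the frequency of the (vast) singleton class, i.e. the
#' natural "just detectable" level.
#'
#' @param values Numeric vector (non-positive entries are ignored; at least
#'   one positive value required).
#' @return The modal positive value.
#' @examples
#' nonzero_mode(c(1, 1, 1, 2, 3))   # 1
#' nonzero_mode(c(2, 2, 3, 3, 9))   # 2 (tie broken toward the smaller value)
#' @export
nonzero_mode <- function(values) {
  values <- values[is.finite(values) & values > 0]
  if (length(values) == 0L) {
    stop("nonzero_mode requires at least one positive value", call. = FALSE)
  }
  u <- sort(unique(values))
  u[which.max(tabulate(match(values, u)))]
}

#' Reference-normalize a depth-normalized screen
#'
#' Divides each peptide's per-read frequency by its frequency in the
#' unselected reference library, cancelling abundance effects that are not
#' target selection: clones over-represented in the naive pool or enriched by
#' fast bacterial amplification appear high in the reference too, so their
#' quotient stays near one. Peptides absent from the reference divide by the
#' reference's non-zero mode instead, so a genuinely new enriched clone
#' (absent background) receives a large, finite value. Peptides absent from
#' the screen itself are not added here; absence is handled at matrix
#' construction by mode imputation.
#'
#' @param screen_depthnorm Named numeric vector from [depth_normalize()].
#' @param reference_depthnorm Named numeric vector for the reference library.
#' @param reference_mode Fallback denominator, normally
#'   `nonzero_mode(reference_depthnorm)`; must be > 0.
#' @param screen_id Label carried into the result.
#' @param total_reads Read depth used, carried into the result.
#' @return An object of class `normalized_screen` with fields `screen_id`,
#'   `values` (all > 0), `total_reads_used`, `nonzero_mode`.
#' @export
reference_normalize <- function(screen_depthnorm, reference_depthnorm,
                                reference_mode = nonzero_mode(reference_depthnorm),
                                screen_id = "screen", total_reads = NA_integer_) {
  if (!is.finite(reference_mode) || reference_mode <= 0) {
    stop("reference_mode must be > 0", call. = FALSE)
  }
  denom <- reference_depthnorm[names(screen_depthnorm)]
  denom[is.na(denom)] <- reference_mode
  values <- screen_depthnorm / denom
  names(values) <- names(screen_depthnorm)
  normalized_screen(screen_id, values, total_reads)
}

normalized_screen <- function(screen_id, values, total_reads = NA_integer_) {
  stopifnot(all(values > 0))
  structure(list(screen_id = screen_id, values = values,
                 total_reads_used = total_reads,
                 nonzero_mode = if (length(values)) nonzero_mode(values) else NA_real_),
            class = "normalized_screen")
}

#' Normalize a set of screens against their reference library
#'
#' Convenience wrapper over [depth_normalize()] and [reference_normalize()]:
#' depth-normalizes every screen, computes the reference's non-zero mode, and
#' reference-normalizes each positive and negative screen. The reference
#' itself is carried as its depth-normalized frequencies (dividing the
#' reference by itself would be uninformative); it appears in the comparison
#' matrix as the background column and takes no part in the ratio.
#'
#' @param tables Named list of [screen_table()] objects (names = screen ids),
#'   covering every id in `assignment`.
#' @param assignment A [role_assignment()].
#' @return Named list of `normalized_screen` objects (reference included).
#' @export
normalize_screens <- function(tables, assignment) {
  ids <- c(assignment$reference, assignment$positives, assignment$negatives)
  missing <- setdiff(ids, names(tables))
  if (length(missing)) {
    stop("configuration error: no screen table for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref_dn <- depth_normalize(tables[[assignment$reference]])
  ref_mode <- nonzero_mode(ref_dn)
  out <- list()
  out[[assignment$reference]] <-
    normalized_screen(assignment$reference, ref_dn,
                      tables[[assignment$reference]]$stats$total_reads)
  for (id in c(assignment$positives, assignment$negatives)) {
    out[[id]] <- reference_normalize(
      depth_normalize(tables[[id]]), ref_dn, ref_mode,
      screen_id = id, total_reads = tables[[id]]$stats$total_reads)
  }
  out
}

#' Build the peptide-by-screen selectivity matrix
#'
#' Rows are the union of peptides observed in any positive or negative
#' screen; columns are the reference followed by the positive and negative
#' screens. A peptide absent from a screen takes that screen's non-zero mode
#' (flagged in the imputation mask) — never zero, which would make the ratio
#' degenerate. Each row's selectivity ratio is the arithmetic mean of its
#' positive cells divided by the arithmetic mean of its negative cells; rows
#' are sorted by ratio, descending, so selective peptides distil to the top.
#'
#' In ubiquitous-binder mode (`ubiquitous = TRUE`) the sort key is instead
#' each row's minimum across all non-reference screens, descending, which
#' surfaces peptides high in every screen (pan-binders / non-specific
#' clones); negatives may then be empty.
#'
#' @param screens Named list of `normalized_screen` objects, e.g. from
#'   [normalize_screens()]; must cover every id in `assignment`.
#' @param assignment A [role_assignment()].
#' @param ubiquitous Rank by minimum across screens instead of the
#'   positive/negative ratio.
#' @return An object of class `selectivity_matrix`: fields `values` (numeric
#'   matrix, rows = peptides, columns = screens), `imputed` (logical mask),
#'   `roles` (per-column role), `ratio`, `positive_mean`, `positive_support`
#'   (per-row count of observed, non-imputed positive cells — the paper-style
#'   "high in at least two positives" evidence), sorted by ratio.
#' @export
build_matrix <- function(screens, assignment, ubiquitous = FALSE) {
  if (!ubiquitous && length(assignment$negatives) == 0L) {
    stop("configuration error: negative screens are required for the ",
         "selectivity ratio (use ubiquitous = TRUE to rank by minimum ",
         "across screens)", call. = FALSE)
  }
  ids <- c(assignment$reference, assignment$positives, assignment$negatives)
  missing <- setdiff(ids, names(screens))
  if (length(missing)) {
    stop("configuration error: no normalized screen for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  comp <- c(assignment$positives, assignment$negatives)
  peptides <- sort(unique(unlist(lapply(screens[comp],
                                        function(s) names(s$values)))))
  if (length(peptides) == 0L) {
    stop("empty-matrix error: no peptides observed in any positive or ",
         "negative screen", call. = FALSE)
  }
  values <- matrix(NA_real_, length(peptides), length(ids),
                   dimnames = list(peptides, ids))
  imputed <- matrix(TRUE, length(peptides), length(ids),
                    dimnames = list(peptides, ids))
  for (id in ids) {
    v <- screens[[id]]$values
    hit <- match(peptides, names(v))
    obs <- !is.na(hit)
    values[obs, id] <- v[hit[obs]]
    values[!obs, id] <- screens[[id]]$nonzero_mode
    imputed[, id] <- !obs
  }
  roles <- c("reference", rep("positive", length(assignment$positives)),
             rep("negative", length(assignment$negatives)))
  names(roles) <- ids
  pos_cols <- ids[roles == "positive"]
  neg_cols <- ids[roles == "negative"]
  pos_mean <- rowMeans(values[, pos_cols, drop = FALSE])
  if (ubiquitous) {
    ratio <- apply(values[, comp, drop = FALSE], 1L, min)
  } else {
    ratio <- pos_mean / rowMeans(values[, neg_cols, drop = FALSE])
  }
  m <- structure(
    list(values = values, imputed = imputed, roles = roles,
         assignment = assignment, ratio = ratio, positive_mean = pos_mean,
         positive_support = rowSums(!imputed[, pos_cols, drop = FALSE]),
         ubiquitous = ubiquitous),
    class = "selectivity_matrix")
  sort_matrix(m)
}

#' Sort a selectivity matrix
#'
#' Stable sort by ratio descending; ties broken by mean positive value
#' descending, then lexicographic peptide order, so output files are
#' deterministic and re-sorting is idempotent.
#'
#' @param matrix A [build_matrix()] result.
#' @return The matrix with rows reordered.
#' @export
sort_matrix <- function(matrix) {
  peps <- rownames(matrix$values)
  ord <- order(-matrix$ratio, -matrix$positive_mean, peps)
  matrix$values <- matrix$values[ord, , drop = FALSE]
  matrix$imputed <- matrix$imputed[ord, , drop = FALSE]
  matrix$ratio <- matrix$ratio[ord]
  matrix$positive_mean <- matrix$positive_mean[ord]
  matrix$positive_support <- matrix$positive_support[ord]
  matrix
}

#' Re-sort processed screens under a new role assignment
#'
#' The same normalized screens can answer a different targeting question —
#' e.g. swapping which cell type counts as the target — without re-reading
#' any FASTQ. Equivalent to [build_matrix()] under the new roles.
#'
#' @inheritParams build_matrix
#' @param new_assignment The new [role_assignment()].
#' @export
resort_with_roles <- function(screens, new_assignment, ubiquitous = FALSE) {
  build_matrix(screens, new_assignment, ubiquitous = ubiquitous)
}

#' @export
print.selectivity_matrix <- function(x, n = 10L, ...) {
  cat("Selectivity matrix: ", nrow(x$values), " peptides x ",
      ncol(x$values), " screens (",
      sum(x$roles == "positive"), " positive, ",
      sum(x$roles == "negative"), " negative)\n", sep = "")
  cat(if (x$ubiquitous) "  ranked by minimum across screens\n" else
    "  ranked by mean(positive) / mean(negative)\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
as.data.frame.selectivity_matrix <- function(x, ...) {
  data.frame(peptide = rownames(x$values), ratio = x$ratio,
             positive_support = x$positive_support,
             as.data.frame(x$values, check.names = FALSE),
             row.names = NULL, check.names = FALSE)
}

#' Round-to-round enrichment of positive screens
#'
#' Ratio of a peptide's mean normalized frequency across positive screens in
#' round two to the same mean in round one, each round normalized against its
#' own reference library. Peptides absent from a screen take that screen's
#' non-zero mode, as in the matrix. Rising clones (ratio well above 1)
#' corroborate target-driven selection independently of the selectivity sort.
#'
#' @param round1,round2 Named lists of `normalized_screen` objects for the
#'   two biopanning rounds (e.g. from [normalize_screens()] with each round's
#'   own reference).
#' @param assignment A [role_assignment()]; only the positive ids are used
#'   (they must exist in both rounds).
#' @return `data.frame` with columns `peptide`, `round1_mean`, `round2_mean`,
#'   `enrichment`, sorted by enrichment descending.
#' @export
round_enrichment <- function(round1, round2, assignment) {
  pos <- assignment$positives
  for (rl in list(round1, round2)) {
    missing <- setdiff(pos, names(rl))
    if (length(missing)) {
      stop("configuration error: positive screen(s) missing from a round: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  peps <- sort(unique(c(
    unlist(lapply(round1[pos], function(s) names(s$values))),
    unlist(lapply(round2[pos], function(s) names(s$values))))))
  if (length(peps) == 0L) {
    warning("no peptides observed in the positive screens of either round")
    return(data.frame(peptide = character(), round1_mean = numeric(),
                      round2_mean = numeric(), enrichment = numeric()))
  }
  round_mean <- function(screens) {
    cells <- vapply(pos, function(id) {
      v <- screens[[id]]$values[peps]
      v[is.na(v)] <- screens[[id]]$nonzero_mode
      v
    }, numeric(length(peps)))
    rowMeans(matrix(cells, nrow = length(peps)))
  }
  m1 <- round_mean(round1)
  m2 <- round_mean(round2)
  out <- data.frame(peptide = peps, round1_mean = m1, round2_mean = m2,
                    enrichment = m2 / m1, row.names = NULL)
  out[order(-out$enrichment, out$peptide), , drop = FALSE]
}

#' Export a selectivity matrix to TSV (plus imputation mask)
#'
#' Writes the sorted matrix as tab-separated text with columns `peptide`,
#' `ratio`, `positive_support`, then one column per screen (reference first,
#' then positives, then negatives). A parallel `*.imputed.tsv` mask marks
#' which cells were mode-imputed rather than observed. Optionally renders a
#' log-scaled heatmap of the top rows via \pkg{pheatmap}.
#'
#' @param matrix A [build_matrix()] result.
#' @param path Output TSV path; the mask is written next to it with
#'   `.imputed.tsv` substituted for `.tsv`.
#' @param top_n Number of top rows to export, or `Inf` for all.
#' @param heatmap Optional PNG path for a heatmap of the exported rows.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path, top_n = Inf, heatmap = NULL) {
  n <- min(nrow(matrix$values), top_n)
  df <- as.data.frame(matrix)[seq_len(n), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mask <- data.frame(peptide = rownames(matrix$imputed)[seq_len(n)],
                     matrix$imputed[seq_len(n), , drop = FALSE],
                     row.names = NULL, check.names = FALSE)
  utils::write.table(mask, sub("\\.tsv$", ".imputed.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(heatmap)) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      warning("pheatmap not installed; skipping heatmap rendering")
    } else {
      grDevices::png(heatmap, width = 900,
                     height = max(300, 18L * n + 120L), res = 110)
      on.exit(grDevices::dev.off(), add = TRUE)
      pheatmap::pheatmap(log10(matrix$values[seq_len(n), , drop = FALSE]),
                         cluster_rows = FALSE, cluster_cols = FALSE,
                         main = "log10 normalized frequency")
    }
  }
  invisible(path)
}
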