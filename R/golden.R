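#' Designed test libraries for the sorting logic
#'
#' A miniature worked example for the selection step: eight 7-mer peptides
#' are assigned a frequency of absent (0), low (10) or high (1000) in a
#' reference library, two positive screens and two negative screens, with an
#' equal total read depth per screen. Each pattern has an obvious qualitative
#' expectation that the ratio sort must reproduce:
#'
#' * `GVTHKLQ` — absent in the reference, high in both positives, absent in
#'   both negatives: the ideal selective clone, ranked first.
#' * `AKNWPQS` — low in one positive, high in the other, absent elsewhere:
#'   selective but weaker, ranked second.
#' * `SSDAALH` — low in the reference, high in every screen: abundant but
#'   completely unselective; its ratio is exactly 1, so it falls to the
#'   unselective block, never the top fraction.
#' * `RVSTPPQ` — high in one positive but also high in one negative:
#'   ratio 1, mid-table.
#' * `AAAWEEK`, `LPNTQFM`, `WHWSWLR` — background clones, low everywhere.
#' * `TPSIYFL` — high only in the negatives: anti-selected, ranked last.
#'
#' @param total_reads Per-screen total read depth (equal across screens).
#' @return List with `tables` (named list of [screen_table()]),
#'   `assignment` (a [role_assignment()]), and `expected_order` (the peptides
#'   in their expected final ranking).
#' @export
designed_test_library <- function(total_reads = 10000L) {
  A <- 0L; L <- 10L; H <- 1000L
  #                 REF  PS1  PS2  NS1  NS2
  design <- rbind(
    GVTHKLQ = c(A, H, H, A, A),
    AKNWPQS = c(A, L, H, A, A),
    SSDAALH = c(L, H, H, H, H),
    RVSTPPQ = c(A, H, A, H, A),
    AAAWEEK = c(L, L, L, L, L),
    LPNTQFM = c(L, L, L, L, L),
    WHWSWLR = c(L, L, L, L, L),
    TPSIYFL = c(A, A, A, H, H)
  )
  colnames(design) <- c("REF", "PS1", "PS2", "NS1", "NS2")
  tables <- lapply(colnames(design), function(id) {
    v <- design[, id]
    screen_table(id, v[v > 0], total_reads = total_reads,
                 scheme_name = "designed")
  })
  names(tables) <- colnames(design)
  list(tables = tables,
       assignment = role_assignment("REF", c("PS1", "PS2"), c("NS1", "NS2")),
       expected_order = c("GVTHKLQ", "AKNWPQS", "SSDAALH", "RVSTPPQ",
                          "AAAWEEK", "LPNTQFM", "WHWSWLR", "TPSIYFL"))
}
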