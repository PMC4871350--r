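test_that("depth normalization divides by total reads and preserves ranking", {
  tab <- screen_table("s", c(a = 100L), total_reads = 1000000L)
  expect_equal(unname(depth_normalize(tab)["a"]), 1e-4)

  tab2 <- screen_table("s", c(a = 2L, b = 1L), total_reads = 4L)
  expect_equal(depth_normalize(tab2), c(a = 0.5, b = 0.25))

  empty <- screen_table("s", stats::setNames(integer(0), character(0)),
                        total_reads = 0L)
  expect_error(depth_normalize(empty), "empty-screen")
})

test_that("reference normalization divides by reference frequency or its mode", {
  out <- reference_normalize(c(p = 1e-4), c(p = 2e-5), reference_mode = 1e-6)
  expect_equal(unname(out$values["p"]), 5)

  out2 <- reference_normalize(c(new = 1e-4), c(other = 2e-5),
                              reference_mode = 1e-6)
  expect_equal(unname(out2$values["new"]), 100)  # absent from reference
  expect_true(all(out2$values > 0))

  expect_error(reference_normalize(c(p = 1e-4), c(p = 2e-5),
                                   reference_mode = 0), "reference_mode")
})

test_that("nonzero_mode returns the plurality value, ties to the smallest", {
  expect_equal(nonzero_mode(c(1, 1, 1, 2, 3)), 1)
  expect_equal(nonzero_mode(c(2, 2, 3, 3, 9)), 2)
  expect_equal(nonzero_mode(7), 7)
  expect_equal(nonzero_mode(c(0, 0, 5, 5, 2)), 5)  # zeros ignored
  expect_error(nonzero_mode(numeric(0)), "positive")
  expect_error(nonzero_mode(c(0, 0)), "positive")
})

test_that("normalization is invariant to uniform depth scaling", {
  set.seed(42)
  counts <- stats::setNames(as.integer(sample(1:500, 40)), paste0("p", 1:40))
  ref <- stats::setNames(as.integer(sample(1:500, 30)), paste0("p", 6:35))
  for (c_mult in c(3L, 17L)) {
    t1 <- screen_table("s", counts, total_reads = 20000L)
    t2 <- screen_table("s", counts * c_mult, total_reads = 20000L * c_mult)
    rt <- screen_table("ref", ref, total_reads = 15000L)
    a <- list(REF = rt, S = t1)
    b <- list(REF = rt, S = t2)
    roles <- role_assignment("REF", "S", character())
    n1 <- normalize_screens(a, roles)$S
    n2 <- normalize_screens(b, roles)$S
    expect_equal(n1$values, n2$values, tolerance = 1e-12)
  }
})

toy_screens <- function() {
  # every peptide present in every screen: imputation-free
  ref <- screen_table("REF", c(a = 10L, b = 10L, c = 10L), total_reads = 100L)
  pos <- screen_table("POS", c(a = 40L, b = 10L, c = 5L), total_reads = 100L)
  neg <- screen_table("NEG", c(a = 5L, b = 10L, c = 40L), total_reads = 100L)
  list(REF = ref, POS = pos, NEG = neg)
}

test_that("ratio is reciprocal under role swap when nothing is imputed", {
  tabs <- toy_screens()
  fwd <- role_assignment("REF", "POS", "NEG")
  rev <- role_assignment("REF", "NEG", "POS")
  m1 <- build_matrix(normalize_screens(tabs, fwd), fwd)
  m2 <- build_matrix(normalize_screens(tabs, rev), rev)
  expect_false(any(m1$imputed[, c("POS", "NEG")]))
  r2 <- m2$ratio[rownames(m1$values)]
  expect_equal(unname(m1$ratio), unname(1 / r2), tolerance = 1e-15)
})

test_that("a peptide present in both roles at equal values has ratio 1", {
  ref <- screen_table("REF", c(x = 10L), total_reads = 100L)
  pos <- screen_table("POS", c(x = 20L), total_reads = 100L)
  neg <- screen_table("NEG", c(x = 20L), total_reads = 100L)
  a <- role_assignment("REF", "POS", "NEG")
  m <- build_matrix(normalize_screens(list(REF = ref, POS = pos, NEG = neg), a), a)
  expect_equal(unname(m$ratio["x"]), 1)
})

test_that("imputed cells take the screen mode: positive but never above the max", {
  tabs <- toy_screens()
  tabs$POS <- screen_table("POS", c(a = 40L, b = 10L, c = 5L, d = 7L),
                           total_reads = 100L)
  a <- role_assignment("REF", "POS", "NEG")
  m <- build_matrix(normalize_screens(tabs, a), a)
  expect_true(m$imputed["d", "NEG"])
  for (col in c("POS", "NEG")) {
    imp <- m$imputed[, col]
    if (any(imp)) {
      expect_true(all(m$values[imp, col] > 0))
      expect_true(all(m$values[imp, col] <= max(m$values[!imp, col])))
    }
  }
  # ratio finite and > 0 everywhere, even for singly-observed peptides
  expect_true(all(is.finite(m$ratio) & m$ratio > 0))
  expect_equal(unname(m$positive_support["d"]), 1)
})

test_that("increasing a positive count never lowers a peptide's ratio or rank", {
  base <- c(a = 30L, b = 20L, c = 10L, d = 5L)
  ref <- screen_table("REF", base, total_reads = 200L)
  neg <- screen_table("NEG", base, total_reads = 200L)
  a <- role_assignment("REF", "POS", "NEG")
  prev_ratio <- -Inf
  prev_rank <- Inf
  for (boost in c(10L, 20L, 60L, 120L)) {
    pos <- screen_table("POS", c(a = 30L, b = 20L, c = boost, d = 5L),
                        total_reads = 200L)
    m <- build_matrix(normalize_screens(list(REF = ref, POS = pos, NEG = neg),
                                        a), a)
    ratio <- m$ratio["c"]
    rank <- which(rownames(m$values) == "c")
    expect_gte(ratio, prev_ratio)
    expect_lte(rank, prev_rank)
    prev_ratio <- ratio
    prev_rank <- rank
  }
})

test_that("sorting is ratio-descending with documented deterministic tie-breaks", {
  g <- designed_test_library()
  screens <- normalize_screens(g$tables, g$assignment)
  m <- build_matrix(screens, g$assignment)
  expect_equal(rownames(m$values), g$expected_order)
  # idempotent
  expect_equal(rownames(sort_matrix(m)$values), g$expected_order)
  # ties at ratio 1 are ordered by mean positive value, then lexicographically
  block <- rownames(m$values)[abs(m$ratio - 1) < 1e-12]
  expect_equal(block, c("SSDAALH", "RVSTPPQ", "AAAWEEK", "LPNTQFM", "WHWSWLR"))
})

test_that("resorting with swapped roles reuses normalized screens", {
  g <- designed_test_library()
  screens <- normalize_screens(g$tables, g$assignment)
  swapped <- role_assignment("REF", c("NS1", "NS2"), c("PS1", "PS2"))
  m2 <- resort_with_roles(screens, swapped)
  expect_equal(rownames(m2$values)[1L], "TPSIYFL")  # anti-target is now the target
  expect_equal(unname(m2$ratio["TPSIYFL"]), 100)
  expect_error(resort_with_roles(screens,
                                 role_assignment("REF", c("PS1", "PS2", "NS1", "NS2"))),
               "negative screens are required")
})

test_that("ubiquitous-binder mode ranks by minimum across screens", {
  g <- designed_test_library()
  screens <- normalize_screens(g$tables, g$assignment)
  all_pos <- role_assignment("REF", c("PS1", "PS2", "NS1", "NS2"))
  m <- build_matrix(screens, all_pos, ubiquitous = TRUE)
  expect_equal(rownames(m$values)[1L], "SSDAALH")  # high in every screen
  expect_equal(unname(m$ratio["SSDAALH"]), 100)    # its worst screen value
})

test_that("round enrichment composes round means with mode imputation", {
  ref1 <- screen_table("REF", c(a = 10L, b = 10L), total_reads = 100L)
  r1 <- screen_table("POS", c(a = 1L, b = 10L), total_reads = 100L)
  ref2 <- screen_table("REF", c(a = 10L, b = 10L), total_reads = 100L)
  r2 <- screen_table("POS", c(a = 35L, b = 10L), total_reads = 100L)
  roles <- role_assignment("REF", "POS", character())
  n1 <- normalize_screens(list(REF = ref1, POS = r1), roles)
  n2 <- normalize_screens(list(REF = ref2, POS = r2), roles)
  enr <- round_enrichment(n1, n2, roles)
  expect_equal(enr$enrichment[enr$peptide == "a"], 35)
  expect_equal(enr$enrichment[enr$peptide == "b"], 1)
  # identical rounds: all ratios 1
  same <- round_enrichment(n1, n1, roles)
  expect_true(all(same$enrichment == 1))
  # absent from round 1: denominator is round-1 mode
  r2b <- screen_table("POS", c(a = 1L, b = 10L, z = 20L), total_reads = 100L)
  n2b <- normalize_screens(list(REF = ref2, POS = r2b), roles)
  enr2 <- round_enrichment(n1, n2b, roles)
  mode1 <- n1$POS$nonzero_mode
  expect_equal(enr2$enrichment[enr2$peptide == "z"],
               unname(n2b$POS$values["z"]) / mode1)
})

test_that("matrix export writes top_n rows and round-trips ratios", {
  g <- designed_test_library()
  m <- build_matrix(normalize_screens(g$tables, g$assignment), g$assignment)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(m, path, top_n = 3)
  df <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), 3L)
  expect_equal(df$peptide, g$expected_order[1:3])
  mask <- utils::read.delim(sub("\\.tsv$", ".imputed.tsv", path),
                            check.names = FALSE)
  expect_equal(nrow(mask), 3L)
  expect_true(is.logical(mask$PS1))

  export_matrix(m, path)  # all rows
  df_all <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(df_all), 8L)
  expect_equal(df_all$ratio, unname(m$ratio), tolerance = 1e-12)
})

test_that("role assignments enforce disjoint, complete groups", {
  expect_error(role_assignment("", "P"), "reference")
  expect_error(role_assignment("R", character()), "positive")
  expect_error(role_assignment("R", "A", "A"), "disjoint")
  expect_error(role_assignment("R", "R"), "disjoint")
})
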