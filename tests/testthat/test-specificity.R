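test_that("sequence harmony endpoints are exact", {
  aln <- toy_alignment()
  # column 1: group A all K, group B all T -> disjoint support
  expect_equal(sequence_harmony(aln, 1), 0)
  # column 2: constant everywhere -> identical distributions
  expect_equal(sequence_harmony(aln, 2), 1)
  # both groups 50/50 on the same two residues -> identical distributions
  mix <- subfamily_alignment(c(a1 = "K", a2 = "T", b1 = "K", b2 = "T"),
                             c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(sequence_harmony(mix, 1), 1)
})

test_that("sequence harmony matches a hand-summed JSD oracle", {
  # group A all K; group B half K half T
  aln <- subfamily_alignment(
    c(a1 = "K", a2 = "K", a3 = "K", a4 = "K",
      b1 = "K", b2 = "K", b3 = "T", b4 = "T"),
    setNames(rep(c("A", "B"), each = 4), c(paste0("a", 1:4), paste0("b", 1:4))))
  want <- oracle_sh(rep("K", 4), c("K", "K", "T", "T"))
  expect_equal(sequence_harmony(aln, 1), want, tolerance = 1e-12)
  # random columns against the oracle
  set.seed(17)
  for (rep in 1:20) {
    resA <- sample(c("K", "T", "R", "S"), 6, replace = TRUE)
    resB <- sample(c("K", "T", "R", "S"), 8, replace = TRUE)
    a <- subfamily_alignment(
      setNames(c(resA, resB), c(paste0("a", 1:6), paste0("b", 1:8))),
      setNames(rep(c("A", "B"), c(6, 8)), c(paste0("a", 1:6), paste0("b", 1:8))))
    expect_equal(sequence_harmony(a, 1), oracle_sh(resA, resB),
                 tolerance = 1e-12)
  }
})

test_that("sequence harmony is symmetric and order-invariant within groups", {
  aln <- toy_alignment()
  swapped <- subfamily_alignment(
    setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln)),
    setNames(ifelse(alignment_groups(aln) == "A", "B", "A"), rownames(aln)))
  perm <- subfamily_alignment(
    setNames(apply(unclass(aln)[c(3, 1, 2, 4, 8, 6, 5, 7), ], 1,
                   paste, collapse = ""),
             rownames(aln)[c(3, 1, 2, 4, 8, 6, 5, 7)]),
    alignment_groups(aln))
  for (j in seq_len(ncol(aln))) {
    expect_equal(sequence_harmony(aln, j), sequence_harmony(swapped, j))
    expect_equal(sequence_harmony(aln, j), sequence_harmony(perm, j))
  }
})

test_that("entirely gapped groups mask the column", {
  aln <- subfamily_alignment(c(a1 = "-K", a2 = "-T", b1 = "KK", b2 = "KT"),
                             c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(is.na(sequence_harmony(aln, 1)))
  sc <- column_scores(aln, iterations = 100L, seed = 1)
  expect_true(sc$masked[1])
  expect_false(sc$masked[2])
})

test_that("multi-RELIEF endpoints: separating and constant columns", {
  aln <- toy_alignment()
  w <- multi_relief(aln, iterations = 2000L, seed = 1)
  expect_equal(w[1], 1)   # perfectly separating column
  expect_equal(w[2], 0)   # constant column
})

test_that("sampled multi-RELIEF matches exhaustive enumeration", {
  aln <- toy_alignment()
  want <- oracle_mr_expectation(aln)
  got <- multi_relief(aln, iterations = 10000L, seed = 1)
  expect_lt(max(abs(got - want)), 0.02)
  # a second toy with ties and 3+5 groups
  seqs <- c(a1 = "KRSTA", a2 = "KRSTG", a3 = "KRATA",
            b1 = "TRSTA", b2 = "TRSTG", b3 = "TRATG", b4 = "TRSTA",
            b5 = "TKSTA")
  aln2 <- subfamily_alignment(seqs, setNames(rep(c("A", "B"), c(3, 5)),
                                             names(seqs)))
  expect_lt(max(abs(multi_relief(aln2, iterations = 10000L, seed = 2) -
                    oracle_mr_expectation(aln2))), 0.02)
})

test_that("multi-RELIEF is deterministic for a fixed seed and needs groups of 2+", {
  aln <- toy_alignment()
  expect_equal(multi_relief(aln, iterations = 500L, seed = 99),
               multi_relief(aln, iterations = 500L, seed = 99))
  single <- subfamily_alignment(c(a1 = "KK", b1 = "TT", b2 = "TK"),
                                c(a1 = "A", b1 = "B", b2 = "B"))
  expect_error(multi_relief(single, iterations = 10L, seed = 1),
               "at least 2")
})

test_that("position selection applies both cutoffs to unmasked columns", {
  sc <- data.frame(column = 1:4,
                   sh = c(0.3, 0.7, 0.3, 0.3),
                   mr = c(0.9, 0.9, 0.7, 0.9),
                   masked = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(select_positions(sc), 1L)
})

test_that("planted specificity columns are recovered with few false positives", {
  aln <- simulate_paralog_alignment(sim_config(14))
  truth <- attr(aln, "spec_columns")
  sc <- column_scores(aln, iterations = 10000L, seed = 14)
  sel <- select_positions(sc)
  expect_gte(sum(truth %in% sel), 8)
  expect_lte(sum(!sel %in% truth), 2)
})

test_that("null alignments yield essentially no selected columns", {
  zero <- vapply(1:100, function(s) {
    cfg <- sim_config(s, n_specificity_columns = 0L, n_group_a = 8L,
                      n_group_b = 8L, aln_length = 120L)
    aln <- simulate_paralog_alignment(cfg)
    sc <- column_scores(aln, iterations = 2000L, seed = s)
    length(select_positions(sc)) == 0L
  }, logical(1L))
  expect_gte(mean(zero), 0.95)
})

test_that("alignment columns map to ungapped residue coordinates", {
  aln <- subfamily_alignment(c(m = "-AK-L", p = "TAKQL"),
                             c(m = "A", p = "B"))
  expect_equal(unname(map_to_paralog_coordinates(aln, c(1, 2, 3, 5), "m")),
               c(NA, 1, 2, 3))
  expect_equal(unname(map_to_paralog_coordinates(aln, 3, "p")), 3)
  expect_error(map_to_paralog_coordinates(aln, 1, "zz"), "unknown")
})

test_that("selected positions partition consistently with domain boundaries", {
  # Mlh3-style domains: ATP binding 1-375, linker 376-488, C-terminal 489-715
  positions <- c(17, 20, 24, 30, 34, 493, 497, 660, 678)
  domains <- cut(positions, c(0, 375, 488, 715),
                 labels = c("Nterm", "linker", "Cterm"))
  expect_equal(as.character(domains[1:5]), rep("Nterm", 5))
  expect_equal(as.character(domains[6:9]), rep("Cterm", 4))
})

test_that("positions group into blocks by linear proximity", {
  b <- group_into_blocks(c(17, 20, 24, 30, 34))
  expect_length(b, 1)
  expect_equal(b[[1]]$span, c(17, 34))
  b2 <- group_into_blocks(c(10, 200))
  expect_length(b2, 2)
  expect_equal(b2[[1]]$positions, 10)
  expect_equal(group_into_blocks(integer(0)), list())
  # blocks are disjoint and ordered
  b3 <- group_into_blocks(c(1, 10, 40, 50, 52, 90), block_gap = 15)
  expect_equal(lapply(b3, `[[`, "positions"),
               list(c(1, 10), c(40, 50, 52), 90))
})

test_that("conserved-column filter applies its three rules", {
  # gap-free fully conserved alignment: everything retained
  aln <- subfamily_alignment(c(a1 = "KKKK", a2 = "KKKK", b1 = "KKKK",
                               b2 = "KKKK"),
                             setNames(rep(c("A", "B"), each = 2),
                                      c("a1", "a2", "b1", "b2")))
  expect_equal(conserved_column_filter(aln), 1:4)
  # a 60%-gap column is dropped along with both neighbours
  seqs <- c(a1 = "KKKKK", a2 = "KK-KK", a3 = "KK-KK",
            b1 = "KK-KK", b2 = "KKKKK")
  aln2 <- subfamily_alignment(seqs, setNames(rep(c("A", "B"), c(3, 2)),
                                             names(seqs)))
  expect_equal(conserved_column_filter(aln2, max_gap_frac = 0.5), c(1, 5))
})

test_that("conserved-column filter matches a rule-by-rule oracle", {
  aln <- simulate_paralog_alignment(sim_config(8, aln_length = 100L,
                                               n_group_a = 6L, n_group_b = 6L,
                                               n_specificity_columns = 0L))
  m <- unclass(aln)
  set.seed(8)
  noisy <- sample(100L, 20L)
  for (j in noisy) m[sample(12L, 8L), j] <- "-"
  aln2 <- subfamily_alignment(
    setNames(apply(m, 1, paste, collapse = ""), rownames(m)),
    alignment_groups(aln))
  got <- conserved_column_filter(aln2, max_gap_frac = 0.5,
                                 min_conservation = 0.6)
  # independent reapplication of the three rules
  gap <- colMeans(m == "-")
  keep <- logical(100L)
  for (j in 1:100) {
    ok_gap <- gap[j] <= 0.5
    ok_nb <- (j == 1 || gap[j - 1] <= 0.5) && (j == 100 || gap[j + 1] <= 0.5)
    res <- m[, j][m[, j] != "-"]
    ok_cons <- length(res) > 0 && max(table(res)) / length(res) >= 0.6
    keep[j] <- ok_gap && ok_nb && ok_cons
  }
  expect_equal(got, which(keep))
})
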