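## Specificity-determining positions between two paralog subfamilies.
##
## Two per-column scores are combined: sequence harmony (sh), the overlap of
## the two groups' residue distributions (1 = identical, 0 = disjoint), and a
## two-group RELIEF weight (mr), which contrasts each sequence's nearest
## within-group neighbour ("hit") with its nearest other-group neighbour
## ("miss"). Columns with mr above and sh below their cutoffs are candidate
## specificity positions; runs of nearby positions form candidate blocks.

# gap-fraction mask: a column is masked when either group is more than
# `mask_gap_frac` gapped (or entirely gapped).
column_mask <- function(aln, mask_gap_frac = 0.5) {
  g <- alignment_groups(aln)
  m <- unclass(aln)
  gapA <- colMeans(m[g == "A", , drop = FALSE] == GAP)
  gapB <- colMeans(m[g == "B", , drop = FALSE] == GAP)
  gapA > mask_gap_frac | gapB > mask_gap_frac
}

# Shannon entropy, base 2, of a probability vector.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sequence-harmony score of one alignment column
#'
#' Residue frequency distributions are computed per group over non-gap
#' symbols; the score is 1 minus the Jensen-Shannon divergence (base-2 logs,
#' equal weights), so identical distributions score 1 and disjoint
#' distributions score 0.
#'
#' @param aln A [subfamily_alignment()].
#' @param column 1-based column index.
#' @return Numeric in \[0, 1\], or NA if either group is entirely gapped.
#' @export
sequence_harmony <- function(aln, column) {
  g <- alignment_groups(aln)
  col <- unclass(aln)[, column]
  resA <- col[g == "A"]; resA <- resA[resA != GAP]
  resB <- col[g == "B"]; resB <- resB[resB != GAP]
  if (length(resA) == 0L || length(resB) == 0L) return(NA_real_)
  pA <- table(factor(resA, levels = AA_ALPHABET)) / length(resA)
  pB <- table(factor(resB, levels = AA_ALPHABET)) / length(resB)
  m <- (pA + pB) / 2
  jsd <- entropy2(m) - (entropy2(pA) + entropy2(pB)) / 2
  1 - max(0, min(1, jsd))
}

# all-column sh scores (NA on masked columns)
sh_scores <- function(aln, mask = column_mask(aln)) {
  vapply(seq_len(ncol(aln)), function(j)
    if (mask[j]) NA_real_ else sequence_harmony(aln, j), numeric(1L))
}

# pairwise similarity (# matching symbols over the given columns; gap matches
# gap) for all sequence pairs.
similarity_matrix <- function(m, cols) {
  n <- nrow(m)
  sub <- m[, cols, drop = FALSE]
  s <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    eq <- sub[rep(i, n - i), , drop = FALSE] == sub[seq.int(i + 1L, n), , drop = FALSE]
    s[i, seq.int(i + 1L, n)] <- rowSums(eq)
  }
  s + t(s)
}

#' Multi-RELIEF column weights
#'
#' Monte-Carlo RELIEF for two groups: each iteration samples a sequence
#' uniformly, finds its nearest hit (same group, excluding itself) and nearest
#' miss (other group) by similarity over unmasked columns (ties broken
#' uniformly at random), and adds, per column, 1 if the miss differs minus 1
#' if the hit differs. Weights are the accumulated sums divided by the number
#' of iterations, so they lie in \[-1, 1\]. Deterministic for a fixed seed.
#'
#' @param aln A [subfamily_alignment()]; both groups need >= 2 sequences.
#' @param iterations Number of sampling iterations (default 10000).
#' @param seed Integer RNG seed (required; recorded by the caller).
#' @param mask_gap_frac Column-masking threshold (default 0.5).
#' @return Numeric vector of per-column weights; NA on masked columns.
#' @export
multi_relief <- function(aln, iterations = 10000L, seed,
                         mask_gap_frac = 0.5) {
  if (missing(seed)) stop("multi_relief requires an explicit seed")
  g <- alignment_groups(aln)
  if (min(table(g)) < 2L)
    stop("each group needs at least 2 sequences (no hit available otherwise)")
  m <- unclass(aln)
  n <- nrow(m)
  L <- ncol(m)
  mask <- column_mask(aln, mask_gap_frac)
  cols <- which(!mask)
  if (length(cols) == 0L) stop("all columns are masked")
  sim <- similarity_matrix(m, cols)
  same <- outer(g, g, "==")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  # candidate hit/miss tie sets per sequence
  hit_ties <- lapply(seq_len(n), function(i) {
    cand <- setdiff(which(same[i, ]), i)
    cand[sim[i, cand] == max(sim[i, cand])]
  })
  miss_ties <- lapply(seq_len(n), function(i) {
    cand <- which(!same[i, ])
    cand[sim[i, cand] == max(sim[i, cand])]
  })
  s_draw <- sample.int(n, iterations, replace = TRUE)
  pick <- function(set) if (length(set) == 1L) set else set[sample.int(length(set), 1L)]
  h_draw <- vapply(s_draw, function(s) pick(hit_ties[[s]]), integer(1L))
  m_draw <- vapply(s_draw, function(s) pick(miss_ties[[s]]), integer(1L))
  acc <- numeric(L)
  add_pairs <- function(a, b, sign) {
    key <- paste(a, b)
    tab <- table(key)
    for (k in names(tab)) {
      ij <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
      acc <<- acc + sign * as.integer(tab[[k]]) * (m[ij[1L], ] != m[ij[2L], ])
    }
  }
  add_pairs(s_draw, m_draw, +1)
  add_pairs(s_draw, h_draw, -1)
  w <- pmax(-1, pmin(1, acc / iterations))
  w[mask] <- NA_real_
  w
}

#' Score all columns of a two-subfamily alignment
#'
#' @param aln A [subfamily_alignment()].
#' @param iterations,seed Passed to [multi_relief()].
#' @param mask_gap_frac Column-masking threshold.
#' @return Data frame: `column` (1-based), `sh`, `mr`, `coverage_a`,
#'   `coverage_b` (fraction non-gap per group), `masked`.
#' @export
column_scores <- function(aln, iterations = 10000L, seed,
                          mask_gap_frac = 0.5) {
  g <- alignment_groups(aln)
  m <- unclass(aln)
  mask <- column_mask(aln, mask_gap_frac)
  data.frame(
    column = seq_len(ncol(m)),
    sh = sh_scores(aln, mask),
    mr = multi_relief(aln, iterations, seed, mask_gap_frac),
    coverage_a = colMeans(m[g == "A", , drop = FALSE] != GAP),
    coverage_b = colMeans(m[g == "B", , drop = FALSE] != GAP),
    masked = mask)
}

#' Select candidate specificity columns
#'
#' A column is selected when its multi-RELIEF weight exceeds `mr_cut` AND its
#' sequence-harmony score is below `sh_cut` (and it is not masked).
#'
#' @param scores Data frame from [column_scores()].
#' @param mr_cut Multi-RELIEF cutoff (default 0.8).
#' @param sh_cut Sequence-harmony cutoff (default 0.5).
#' @return Integer vector of selected 1-based column indices.
#' @export
select_positions <- function(scores, mr_cut = 0.8, sh_cut = 0.5) {
  sel <- !scores$masked & !is.na(scores$mr) & !is.na(scores$sh) &
    scores$mr > mr_cut & scores$sh < sh_cut
  scores$column[sel]
}

#' Map alignment columns to ungapped residue numbers of one sequence
#'
#' @param aln A [subfamily_alignment()].
#' @param columns 1-based alignment column indices.
#' @param member_id Sequence id whose coordinate system is wanted.
#' @return Named integer vector (names = column indices) of 1-based ungapped
#'   residue numbers; NA where the sequence is gapped at that column.
#' @export
map_to_paralog_coordinates <- function(aln, columns, member_id) {
  if (!member_id %in% rownames(aln))
    stop("unknown sequence id: ", member_id)
  row <- unclass(aln)[member_id, ]
  resno <- cumsum(row != GAP)
  out <- ifelse(row[columns] == GAP, NA_integer_, resno[columns])
  names(out) <- columns
  out
}

#' Group residue positions into linear-proximity blocks
#'
#' Maximal runs of sorted positions whose successive gaps are at most
#' `block_gap` residues; a linear stand-in for grouping by 3D proximity on a
#' structure.
#'
#' @param positions Integer residue positions (will be sorted; NA dropped).
#' @param block_gap Maximum allowed gap between successive members (default
#'   15).
#' @return List of blocks, each a list with `positions` and `span`
#'   (first..last residue).
#' @export
group_into_blocks <- function(positions, block_gap = 15L) {
  positions <- sort(unique(positions[!is.na(positions)]))
  if (length(positions) == 0L) return(list())
  brk <- c(0L, which(diff(positions) > block_gap), length(positions))
  lapply(seq_len(length(brk) - 1L), function(k) {
    p <- positions[seq.int(brk[k] + 1L, brk[k + 1L])]
    list(positions = p, span = c(min(p), max(p)))
  })
}

#' Conserved-column filter
#'
#' A simplified conserved-block selector in the spirit of alignment trimmers:
#' a column is retained when (1) its gap fraction is at most `max_gap_frac`,
#' (2) neither adjacent column exceeds `max_gap_frac`, and (3) its
#' majority-residue frequency among non-gap symbols is at least
#' `min_conservation`.
#'
#' @param aln A [subfamily_alignment()].
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.2).
#' @param min_conservation Minimum majority-residue frequency (default 0.5).
#' @return Integer vector of retained 1-based column indices.
#' @export
conserved_column_filter <- function(aln, max_gap_frac = 0.2,
                                    min_conservation = 0.5) {
  m <- unclass(aln)
  L <- ncol(m)
  gap_frac <- colMeans(m == GAP)
  gappy <- gap_frac > max_gap_frac
  # retained columns must not be gappy nor adjacent to a gappy column
  left_bad  <- c(FALSE, gappy[-L])
  right_bad <- c(gappy[-1L], FALSE)
  cons <- vapply(seq_len(L), function(j) {
    res <- m[, j]; res <- res[res != GAP]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(res)
  }, numeric(1L))
  which(!gappy & !left_bad & !right_bad & cons >= min_conservation)
}
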