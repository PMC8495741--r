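## Evolutionary rate covariation (ERC): Winsorized Pearson correlation of two
## genes' RER profiles over shared branches, plus an empirical p-value built
## from a reference panel of genes.

#' Winsorize an RER vector
#'
#' Robustifies the ERC correlation against outlier branches by limiting the
#' two most extreme positive and the two most extreme negative values to the
#' third most extreme value of the same tail. "Most extreme" is by rank (order
#' statistics, stable ties): the two largest entries are set to the third
#' largest value, the two smallest to the third smallest. Clipping is applied
#' only when the vector has at least 5 finite entries and at least 3 distinct
#' finite values; shorter or near-constant vectors pass through unchanged.
#'
#' @param x Numeric vector (element order is preserved).
#' @return The clipped vector, same length and order.
#' @export
winsorize_rer <- function(x) {
  fin <- which(is.finite(x))
  if (length(fin) < 5L) return(x)
  v <- x[fin]
  if (length(unique(v)) < 3L) return(x)
  out <- x
  ord_up <- order(v, decreasing = TRUE)       # stable ties
  out[fin[ord_up[1:2]]] <- pmin(v[ord_up[1:2]], v[ord_up[3L]])
  ord_lo <- order(v)
  out[fin[ord_lo[1:2]]] <- pmax(v[ord_lo[1:2]], v[ord_lo[3L]])
  out
}

#' ERC between two RER profiles
#'
#' Pearson correlation of the two Winsorized RER vectors restricted to their
#' shared branches.
#'
#' @param rer_a,rer_b `rer_profile` objects.
#' @param min_branches Minimum shared branches (default 10).
#' @return List with `pair` (gene names), `erc` (in \[-1, 1\], NA when either
#'   vector has zero variance after Winsorization) and `n_branches`.
#' @export
erc_pair <- function(rer_a, rer_b, min_branches = 10L) {
  shared <- intersect(rer_a$branches, rer_b$branches)
  if (length(shared) < min_branches)
    stop(sprintf("pair (%s, %s) shares %d branches; %d required",
                 rer_a$gene, rer_b$gene, length(shared), min_branches))
  wa <- winsorize_rer(rer_a$rer[shared])
  wb <- winsorize_rer(rer_b$rer[shared])
  # variance at numerical-noise level (degenerate profiles) is treated as zero
  erc <- if (stats::sd(wa) < 1e-12 || stats::sd(wb) < 1e-12) NA_real_
         else stats::cor(wa, wb)
  list(pair = c(rer_a$gene, rer_b$gene), erc = erc,
       n_branches = length(shared))
}

#' Pairwise ERC matrix
#'
#' @param profiles Named list of `rer_profile`s (>= 2).
#' @param min_branches Passed to [erc_pair()].
#' @return Symmetric numeric matrix of ERC values; diagonal 1 by convention,
#'   NA where undefined.
#' @export
erc_matrix <- function(profiles, min_branches = 10L) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  genes <- vapply(profiles, function(p) p$gene, character(1L))
  k <- length(profiles)
  m <- diag(1, k)
  dimnames(m) <- list(genes, genes)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    e <- erc_pair(profiles[[i]], profiles[[j]], min_branches)$erc
    m[i, j] <- e
    m[j, i] <- e
  }
  m
}

#' Empirical p-value for an observed ERC
#'
#' The null distribution is the set of ERC values of each focal gene against
#' every gene of a reference panel (pooled over both focal genes); the
#' p-value uses the add-one rank formula p = (1 + #\{null >= observed\}) /
#' (1 + null size), so p is never exactly 0.
#'
#' @param rer_a,rer_b Focal `rer_profile`s.
#' @param reference_profiles List of reference `rer_profile`s; a panel smaller
#'   than `min_refs` triggers a warning (the p is still returned with its null
#'   size).
#' @param min_branches Passed to [erc_pair()].
#' @param min_refs Panel size below which a warning is raised (default 50).
#' @return List with `erc`, `p`, `null_size`, `n_branches`.
#' @export
empirical_p <- function(rer_a, rer_b, reference_profiles,
                        min_branches = 10L, min_refs = 50L) {
  if (length(reference_profiles) < min_refs)
    warning(sprintf("only %d reference profiles (< %d); empirical p is coarse",
                    length(reference_profiles), min_refs))
  obs <- erc_pair(rer_a, rer_b, min_branches)
  if (is.na(obs$erc)) return(list(erc = NA_real_, p = NA_real_,
                                  null_size = 0L, n_branches = obs$n_branches))
  null <- c(panel_ercs(rer_a, reference_profiles, min_branches),
            panel_ercs(rer_b, reference_profiles, min_branches))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= obs$erc)) / (1 + length(null))
  list(erc = obs$erc, p = p, null_size = length(null),
       n_branches = obs$n_branches)
}

# ERC of one profile against each member of a panel, batching panel members
# that share an identical branch set so Winsorization and correlation run on
# matrices instead of one pair at a time. Pairs with too few shared branches
# or zero variance give NA.
panel_ercs <- function(p, panel, min_branches = 10L) {
  sig <- vapply(panel, function(r) paste(sort(r$branches), collapse = "\r"),
                character(1L))
  out <- rep(NA_real_, length(panel))
  for (s in unique(sig)) {
    idx <- which(sig == s)
    shared <- intersect(p$branches, panel[[idx[1L]]]$branches)
    if (length(shared) < min_branches) next
    wp <- winsorize_rer(p$rer[shared])
    if (stats::sd(wp) < 1e-12) next
    W <- vapply(panel[idx], function(r) winsorize_rer(r$rer[shared]),
                numeric(length(shared)))
    W <- matrix(W, nrow = length(shared))
    ok <- apply(W, 2L, stats::sd) >= 1e-12
    if (any(ok))
      out[idx[ok]] <- as.vector(stats::cor(wp, W[, ok, drop = FALSE]))
  }
  out
}

#' Full ERC analysis table with empirical p-values
#'
#' @param profiles Named list of focal `rer_profile`s.
#' @param reference_profiles Reference panel for the empirical null.
#' @param min_branches,min_refs Passed through.
#' @return Data frame: `gene_a`, `gene_b`, `erc`, `n_branches`, `p`,
#'   `null_size`, one row per unordered pair.
#' @export
erc_analysis <- function(profiles, reference_profiles,
                         min_branches = 10L, min_refs = 50L) {
  k <- length(profiles)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    r <- empirical_p(profiles[[i]], profiles[[j]], reference_profiles,
                     min_branches, min_refs)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = profiles[[i]]$gene, gene_b = profiles[[j]]$gene,
      erc = r$erc, n_branches = r$n_branches, p = r$p,
      null_size = r$null_size, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an ERC matrix with p-values in the classic layout
#'
#' ERC values above the diagonal, empirical p-values below, 1 on the diagonal.
#'
#' @param analysis Data frame from [erc_analysis()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_erc_matrix <- function(analysis, path) {
  genes <- unique(c(analysis$gene_a, analysis$gene_b))
  k <- length(genes)
  m <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  diag(m) <- 1
  for (r in seq_len(nrow(analysis))) {
    i <- match(analysis$gene_a[r], genes)
    j <- match(analysis$gene_b[r], genes)
    m[min(i, j), max(i, j)] <- analysis$erc[r]
    m[max(i, j), min(i, j)] <- analysis$p[r]
  }
  df <- data.frame(gene = genes, m, check.names = FALSE)
  write_tsv_table(df, path)
}
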