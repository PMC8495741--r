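## Relative evolutionary rates (RERs).
##
## Branch lengths are variance-stabilized with a square-root transform; the
## normalization vector is the per-branch mean transformed length across a
## reference panel of genes; each gene is then projected onto the
## normalization vector by least squares through the origin and the residuals
## are its RERs. All downstream ERC correlations are invariant to a gene's
## overall rate because rescaling raw lengths by c scales the whole residual
## vector by sqrt(c).

#' Estimate the branch-rate normalization vector from reference gene trees
#'
#' @param trees A [gene_tree_set()] of reference genes (>= 10 genes).
#' @param min_support Minimum number of reference genes that must carry a
#'   branch for it to enter the normalization vector (default 5).
#' @return An object of class `rer_norm`: list with `a` (named per-branch mean
#'   square-root-transformed length) and `support` (contributing gene count).
#' @export
estimate_normalization <- function(trees, min_support = 5L) {
  if (!inherits(trees, "gene_tree_set")) stop("trees must be a gene_tree_set")
  b <- trees$branches
  if (ncol(b) < 1L) stop("empty reference set")
  if (ncol(b) < 10L)
    warning("fewer than 10 reference genes; normalization will be noisy")
  s <- sqrt(b)
  support <- rowSums(!is.na(s))
  a <- rowMeans(s, na.rm = TRUE)
  keep <- support >= min_support
  if (!any(keep)) stop("no branch reaches min_support = ", min_support)
  structure(list(a = a[keep], support = support[keep]), class = "rer_norm")
}

#' Compute the relative-evolutionary-rate profile of one gene
#'
#' Fits the gene's square-root-transformed branch lengths x_b against the
#' normalization vector a_b by least squares through the origin; the residuals
#' x_b - beta * a_b are the gene's RERs.
#'
#' @param gene_branches Named numeric vector of raw branch lengths keyed by
#'   branch identifier (NA for branches the gene lacks), or a single-column
#'   selection from a `gene_tree_set`'s `branches` matrix.
#' @param norm An `rer_norm` normalization vector.
#' @param gene Gene name for the profile (default "gene").
#' @param min_branches Minimum shared branches required (default 10).
#' @return An object of class `rer_profile`: list with `gene`, `rer` (named
#'   residual vector over shared branches), `beta` (scaling coefficient), and
#'   `branches` (branch identifiers used).
#' @export
compute_rer <- function(gene_branches, norm, gene = "gene",
                        min_branches = 10L) {
  if (!inherits(norm, "rer_norm")) stop("norm must be an rer_norm")
  shared <- intersect(names(norm$a), names(gene_branches)[!is.na(gene_branches)])
  if (length(shared) < min_branches)
    stop(sprintf("gene '%s' shares %d branches with the normalization vector; %d required",
                 gene, length(shared), min_branches))
  x <- sqrt(gene_branches[shared])
  a <- norm$a[shared]
  denom <- sum(a * a)
  if (denom == 0) stop("normalization vector is identically zero on shared branches")
  beta <- sum(x * a) / denom
  structure(list(gene = gene, rer = x - beta * a, beta = beta,
                 branches = shared),
            class = "rer_profile")
}

#' @export
print.rer_profile <- function(x, ...) {
  cat(sprintf("rer_profile '%s': %d branches, beta = %.4g\n",
              x$gene, length(x$rer), x$beta))
  invisible(x)
}

#' Compute RER profiles for every gene of a set
#'
#' @param trees A [gene_tree_set()].
#' @param norm An `rer_norm`.
#' @param min_branches Passed to [compute_rer()].
#' @return Named list of `rer_profile` objects.
#' @export
compute_rer_set <- function(trees, norm, min_branches = 10L) {
  genes <- colnames(trees$branches)
  profs <- lapply(genes, function(g)
    compute_rer(trees$branches[, g], norm, gene = g,
                min_branches = min_branches))
  names(profs) <- genes
  profs
}

#' Write RER profiles as a branch x gene TSV matrix
#' @param profiles Named list of `rer_profile`s.
#' @param path Output TSV (first column `branch`, one column per gene, NA for
#'   branches a gene lacks).
#' @return `path`, invisibly.
#' @export
write_rer_matrix <- function(profiles, path) {
  keys <- sort(unique(unlist(lapply(profiles, function(p) p$branches))))
  m <- vapply(profiles, function(p) {
    v <- rep(NA_real_, length(keys)); names(v) <- keys
    v[p$branches] <- p$rer
    v
  }, numeric(length(keys)))
  df <- data.frame(branch = keys, m, check.names = FALSE)
  write_tsv_table(df, path)
}

#' Read RER profiles from a branch x gene TSV matrix
#' @param path TSV written by [write_rer_matrix()].
#' @return Named list of `rer_profile`s (with `beta = NA`, unknown after
#'   serialization).
#' @export
read_rer_matrix <- function(path) {
  df <- read_tsv_table(path)
  keys <- df$branch
  genes <- setdiff(names(df), "branch")
  profs <- lapply(genes, function(g) {
    v <- df[[g]]
    names(v) <- keys
    v <- v[!is.na(v)]
    structure(list(gene = g, rer = v, beta = NA_real_, branches = names(v)),
              class = "rer_profile")
  })
  names(profs) <- genes
  profs
}
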