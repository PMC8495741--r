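## Meiotic crossover analysis from spore-autonomous fluorescence tetrad
## counts. Crossover activity in a two-marker interval is summarized as
## percent tetratype, 100 * TT / (TT + PD); each allele is compared to a
## functional (wild-type-like) reference and a null reference with Pearson
## chi-squared tests on the 2x2 count tables, all p-values enter one
## Benjamini-Hochberg family, and a three-way call is made.

#' Percent tetratype
#'
#' @param tt Tetratype count.
#' @param pd Parental ditype count. `tt + pd` must be positive.
#' @return 100 * tt / (tt + pd). Reporting functions round to 1 decimal.
#' @export
percent_tetratype <- function(tt, pd) {
  if (any(tt + pd <= 0)) stop("tt + pd must be positive")
  100 * tt / (tt + pd)
}

#' Pearson chi-squared test on a 2x2 tetrad table
#'
#' Compares TT/PD proportions of two genotypes with the Pearson statistic
#' (1 df). No continuity correction by default, matching the plain Pearson
#' test; Yates correction is available behind `correct`.
#'
#' @param tt1,pd1 Counts for the first genotype.
#' @param tt2,pd2 Counts for the second genotype.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `statistic` and `p`.
#' @export
chi2_2x2 <- function(tt1, pd1, tt2, pd2, correct = FALSE) {
  tab <- matrix(c(tt1, pd1, tt2, pd2), nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Benjamini-Hochberg step-up significance at FDR q
#'
#' Step-up rule: with sorted p-values p_(1) <= ... <= p_(m), find the largest
#' k with p_(k) <= k q / m; all p-values at most p_(k) are significant. The
#' reported cutoff is p_(k) (NA when nothing is significant).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @return List with `significant` (logical mask, input order) and `cutoff`
#'   (largest significant raw p-value, NA if none).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L)
    return(list(significant = logical(0L), cutoff = NA_real_))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  sig <- !is.na(adj) & adj <= q
  cutoff <- if (any(sig)) max(pvalues[sig]) else NA_real_
  list(significant = sig, cutoff = cutoff)
}

#' Classify one allele against functional and null references
#'
#' With BH-adjusted significance of the allele-vs-reference tests:
#' significant only against the null reference -> "+" (wild-type-like);
#' significant only against the functional reference -> "-" (null-like);
#' significant against both -> "+/-" (intermediate); significant against
#' neither -> "indeterminate".
#'
#' @param sig_vs_wt,sig_vs_null Logical BH significance of the two
#'   comparisons.
#' @return One of "+", "-", "+/-", "indeterminate".
#' @export
classify_allele <- function(sig_vs_wt, sig_vs_null) {
  if (sig_vs_wt && sig_vs_null) "+/-"
  else if (sig_vs_null) "+"
  else if (sig_vs_wt) "-"
  else "indeterminate"
}

#' Crossover calls for a tetrad count table
#'
#' Each non-reference genotype is chi-squared-tested against the wild-type
#' and null reference genotypes; all p-values (both comparisons for every
#' allele) form one BH family at FDR `q`, and each allele receives a
#' [classify_allele()] call.
#'
#' @param counts A [tetrad_table()] including the two reference genotypes.
#' @param wt Genotype id of the functional (wild-type) reference.
#' @param null Genotype id of the null reference.
#' @param q FDR for the BH family (default 0.05).
#' @param correct Yates correction flag for [chi2_2x2()] (default FALSE).
#' @return Data frame: `genotype`, `TT`, `PD`, `n`, `percent_tt` (1 decimal),
#'   `p_vs_wt`, `p_vs_null`, `bh_sig_vs_wt`, `bh_sig_vs_null`, `call`; plus
#'   attribute `bh_cutoff`.
#' @export
tetrad_calls <- function(counts, wt, null, q = 0.05, correct = FALSE) {
  counts <- tetrad_table(as.data.frame(counts))
  gt <- counts$genotype
  if (!wt %in% gt) stop("wild-type reference '", wt, "' not in table")
  if (!null %in% gt) stop("null reference '", null, "' not in table")
  wt_row <- counts[match(wt, gt), ]
  null_row <- counts[match(null, gt), ]
  alleles <- counts[!(gt %in% c(wt, null)), , drop = FALSE]
  p_wt <- vapply(seq_len(nrow(alleles)), function(i)
    chi2_2x2(alleles$TT[i], alleles$PD[i], wt_row$TT, wt_row$PD,
             correct = correct)$p, numeric(1L))
  p_null <- vapply(seq_len(nrow(alleles)), function(i)
    chi2_2x2(alleles$TT[i], alleles$PD[i], null_row$TT, null_row$PD,
             correct = correct)$p, numeric(1L))
  bh <- bh_adjust(c(p_wt, p_null), q = q)
  k <- nrow(alleles)
  sig_wt <- bh$significant[seq_len(k)]
  sig_null <- bh$significant[k + seq_len(k)]
  call <- vapply(seq_len(k), function(i)
    classify_allele(sig_wt[i], sig_null[i]), character(1L))
  out <- data.frame(
    genotype = alleles$genotype, TT = alleles$TT, PD = alleles$PD,
    n = alleles$n,
    percent_tt = round(percent_tetratype(alleles$TT, alleles$PD), 1L),
    p_vs_wt = p_wt, p_vs_null = p_null,
    bh_sig_vs_wt = sig_wt, bh_sig_vs_null = sig_null,
    call = call, stringsAsFactors = FALSE)
  attr(out, "bh_cutoff") <- bh$cutoff
  out
}
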