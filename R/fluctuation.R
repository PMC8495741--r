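## Fluctuation-assay mutation rates by the method of the median.
##
## The working equation is Drake's median-based estimator mu = f / ln(N * mu),
## where f is the median per-culture mutant frequency and N the (median)
## number of viable cells per culture. The equation is solved for mu on its
## increasing branch; 95% confidence intervals come from nonparametric
## order-statistic ranks on the per-culture frequencies.

#' Solve the median-method equation mu = f / ln(N mu)
#'
#' Finds the unique mu with N mu > 1 satisfying mu * ln(N * mu) = f, by
#' bracketed bisection followed by a fixed-point polish (relative tolerance
#' 1e-12).
#'
#' @param f Median mutant frequency (dimensionless, >= 0).
#' @param N Viable cells per culture (> 0).
#' @return mu, mutations per cell per generation. `f = 0` returns 0 with
#'   attribute `flag = "no revertants"`. `0 < f <= e/N` (no root on the
#'   meaningful branch) is an error.
#' @export
solve_drake <- function(f, N) {
  stopifnot(length(f) == 1L, length(N) == 1L, N > 0, f >= 0)
  if (f == 0) return(structure(0, flag = "no revertants"))
  if (f <= exp(1) / N)
    stop("no root with N*mu > e exists: f <= e/N (f = ", f, ", N = ", N, ")")
  g <- function(mu) mu * log(N * mu)
  lo <- exp(1) / N            # g(lo) = e/N < f
  hi <- max(f, 2 * exp(1) / N)
  while (g(hi) < f) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < f) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-12) break
  }
  mu <- (lo + hi) / 2
  for (i in 1:50) {           # contraction for N*mu > e
    mu_new <- f / log(N * mu)
    if (abs(mu_new - mu) <= 1e-14 * mu) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

#' Nonparametric 95% CI ranks for a median
#'
#' Order-statistic ranks for an approximate 95% confidence interval on the
#' median of n values: lower rank floor((n - 1.96 sqrt(n)) / 2), upper rank
#' ceiling(1 + (n + 1.96 sqrt(n)) / 2), both clamped to \[1, n\].
#'
#' @param n Number of cultures (>= 6 for a defined CI).
#' @return Integer vector `c(lower, upper)` of ranks, or NAs with attribute
#'   `flag = "n too small"` when n < 6.
#' @export
ci95_median_ranks <- function(n) {
  if (n < 6L) return(structure(c(NA_integer_, NA_integer_),
                               flag = "n too small"))
  lo <- floor((n - 1.96 * sqrt(n)) / 2)
  hi <- ceiling(1 + (n + 1.96 * sqrt(n)) / 2)
  c(max(1L, as.integer(lo)), min(n, as.integer(hi)))
}

#' Order-statistic 95% CI on the median of per-culture values
#'
#' @param x Numeric per-culture values (any order).
#' @return List with `low`, `high` (the order statistics at the
#'   [ci95_median_ranks()] ranks) and `ranks`; NAs when n < 6.
#' @export
ci95_median <- function(x) {
  n <- length(x)
  r <- ci95_median_ranks(n)
  if (anyNA(r)) return(list(low = NA_real_, high = NA_real_, ranks = r))
  s <- sort(x)
  list(low = s[r[1L]], high = s[r[2L]], ranks = r)
}

#' Estimate a mutation rate from one strain's culture table
#'
#' Per-culture frequencies f_i = r_i / N_i are reduced to their median f and
#' the median viable count N; mu solves mu = f / ln(N mu). The 95% CI applies
#' the order-statistic ranks to the per-culture frequencies and maps the
#' bracketing frequencies to rates through the same equation at the median N
#' (monotone in f, so ci_low <= mu <= ci_high). Bracketing frequencies of 0,
#' or at most e/N (where the equation has no meaningful root), give a CI bound
#' of 0 and a flag.
#'
#' @param table A [culture_table()] for a single strain (>= 5 cultures).
#' @return An object of class `rate_estimate`: list with `strain`, `mu`, `f`,
#'   `N`, `ci_low`, `ci_high`, `n_cultures`, `flags`.
#' @export
estimate_rate <- function(table) {
  table <- culture_table(as.data.frame(table))
  if (length(unique(table$strain)) != 1L)
    stop("estimate_rate expects a single strain; see fluctuation_analysis()")
  n <- nrow(table)
  if (n < 5L) stop("at least 5 cultures required (got ", n, ")")
  f_i <- table$revertants / table$viable
  f <- stats::median(f_i)
  N <- stats::median(table$viable)
  flags <- character(0L)
  rate_from_f <- function(fv) {
    if (fv == 0) return(0)
    if (fv <= exp(1) / N) return(NA_real_)
    solve_drake(fv, N)
  }
  mu <- rate_from_f(f)
  if (f == 0) flags <- c(flags, "no revertants")
  else if (is.na(mu)) {
    flags <- c(flags, "median frequency at or below e/N; rate reported as 0")
    mu <- 0
  }
  ci <- ci95_median(f_i)
  if (anyNA(c(ci$low, ci$high))) {
    flags <- c(flags, "CI undefined (n < 6)")
    ci_low <- NA_real_; ci_high <- NA_real_
  } else {
    ci_low <- rate_from_f(ci$low)
    ci_high <- rate_from_f(ci$high)
    if (is.na(ci_low)) { ci_low <- 0; flags <- c(flags, "lower CI frequency below e/N; bound reported as 0") }
    if (is.na(ci_high)) { ci_high <- 0; flags <- c(flags, "upper CI frequency below e/N; bound reported as 0") }
  }
  structure(list(strain = table$strain[1L], mu = as.numeric(mu), f = f, N = N,
                 ci_low = ci_low, ci_high = ci_high, n_cultures = n,
                 flags = flags),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate '%s': mu = %.3g [%.3g, %.3g], n = %d%s\n",
              x$strain, x$mu, x$ci_low, x$ci_high, x$n_cultures,
              if (length(x$flags)) paste0(" (", paste(x$flags, collapse = "; "), ")")
              else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two samples of per-culture rates or frequencies.
#' Uses the exact null distribution when min(n_a, n_b) <= 8 and there are no
#' ties, and the normal approximation with tie and continuity corrections
#' otherwise (the corrected approximation tracks the exact branch to about
#' 0.01 at n = 8).
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   1/2) and `p` (two-sided).
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # zero-variance normal approximation (all ties)
  list(U = U, p = min(1, p))
}

#' Rate relative to a reference strain
#'
#' @param mu_strain,mu_reference Mutation rates; the reference must be > 0.
#' @return List with `raw` (the exact ratio) and `rounded` (3 significant
#'   figures, ties rounded half to even).
#' @export
relative_rate <- function(mu_strain, mu_reference) {
  if (mu_reference <= 0) stop("reference rate must be positive")
  raw <- mu_strain / mu_reference
  list(raw = raw, rounded = signif(raw, 3))
}

#' Fluctuation analysis of a multi-strain culture table
#'
#' Estimates each strain's rate, compares it to a reference strain, and
#' reports relative rates and Mann-Whitney p-values.
#'
#' @param table A [culture_table()] with one or more strains.
#' @param reference Strain id used as the denominator (default "WT").
#' @return Data frame: `strain`, `n`, `mu`, `ci_low`, `ci_high`,
#'   `relative_to_reference` (3 significant figures), `relative_raw`,
#'   `mann_whitney_p_vs_reference`.
#' @export
fluctuation_analysis <- function(table, reference = "WT") {
  table <- culture_table(as.data.frame(table))
  strains <- unique(table$strain)
  if (!reference %in% strains)
    stop("reference strain '", reference, "' not in table")
  est <- lapply(strains, function(s)
    estimate_rate(table[table$strain == s, , drop = FALSE]))
  names(est) <- strains
  ref <- est[[reference]]
  f_ref <- with(table[table$strain == reference, ],
                revertants / viable)
  rows <- lapply(strains, function(s) {
    e <- est[[s]]
    rel <- relative_rate(e$mu, ref$mu)
    f_s <- with(table[table$strain == s, ], revertants / viable)
    p <- if (s == reference) 1 else mann_whitney(f_s, f_ref)$p
    data.frame(strain = s, n = e$n_cultures, mu = e$mu,
               ci_low = e$ci_low, ci_high = e$ci_high,
               relative_to_reference = rel$rounded, relative_raw = rel$raw,
               mann_whitney_p_vs_reference = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
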