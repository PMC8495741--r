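## Synthetic-data generators. Every input the pipeline consumes can be
## simulated with the statistical structure the analyses assume: gene trees
## with tunable rate covariation on a fixed 18-taxon fungal species panel,
## Luria-Delbruck fluctuation cultures, binomial tetrad draws, and
## two-subfamily alignments with planted specificity columns.

# Evaluate expr under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sub-stream seed derived from a master seed, kept below 2^31
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' The packaged 18-taxon master species tree
#'
#' A fixed fungal species panel (Saccharomycetaceae plus the CTG clade) with
#' arbitrary but fixed branch lengths, used as the shared topology for all
#' simulated gene and domain trees.
#'
#' @return A `phylo` tree with 18 tips.
#' @export
master_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((((((Scer:0.05,Spar:0.05):0.03,Smik:0.08):0.02,Sbay:0.09):0.05,",
    "(Ncas:0.12,Cgla:0.13):0.04):0.03,Vpol:0.16):0.04,",
    "(((Lklu:0.10,(Lthe:0.08,Lwal:0.09):0.03):0.04,",
    "(Klac:0.12,Egos:0.14):0.05):0.06,",
    "((((Ctro:0.07,(Calb:0.04,Cdub:0.04):0.03):0.04,Clus:0.11):0.02,",
    "Cgui:0.12):0.05,Dhan:0.15):0.10):0.02);"))
}

#' Simulation configuration
#'
#' Bundles the parameters of all four generators with one master seed. Each
#' generator derives its own sub-streams so outputs stay stable when other
#' counts change.
#'
#' @param seed Integer master seed (recorded in all outputs).
#' @param master `phylo` master topology (default [master_species_tree()]).
#' @param n_reference_genes Reference panel size for rate normalization
#'   (default 150).
#' @param beta_sdlog Log-normal sd of per-gene rate scaling (default 0.3).
#' @param sigma Branch-deviation sd on the square-root scale (default 0.05).
#' @param rho Pairwise covariation mixing for designated gene pairs, in
#'   \[0, 1\] (default 0).
#' @param n_pairs Number of focal covarying gene pairs to simulate (default 1).
#' @param mu True mutation rate per cell per generation (default 1e-7).
#' @param N0 Inoculum size per culture (default 1000 cells).
#' @param N_final Target final viable count (default 2e8 cells).
#' @param n_cultures Parallel cultures per strain (default 30).
#' @param p_tt Tetratype probability per tetrad (default 0.371).
#' @param n_tetrads Tetrads scored (default 1000).
#' @param n_group_a,n_group_b Alignment subfamily sizes (defaults 29 and 34,
#'   the Mlh3/Pms1 panel sizes).
#' @param aln_length Alignment length in columns (default 300).
#' @param n_specificity_columns Planted specificity columns (default 10).
#' @param background_conservation Majority-residue frequency of background
#'   columns (default 0.7).
#' @param specificity_conservation Within-group conservation of planted
#'   columns (default 0.9).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       master = master_species_tree(),
                       n_reference_genes = 150L,
                       beta_sdlog = 0.3,
                       sigma = 0.05,
                       rho = 0,
                       n_pairs = 1L,
                       mu = 1e-7,
                       N0 = 1e3,
                       N_final = 2e8,
                       n_cultures = 30L,
                       p_tt = 0.371,
                       n_tetrads = 1000L,
                       n_group_a = 29L,
                       n_group_b = 34L,
                       aln_length = 300L,
                       n_specificity_columns = 10L,
                       background_conservation = 0.7,
                       specificity_conservation = 0.9) {
  stopifnot(rho >= 0, rho <= 1, p_tt >= 0, p_tt <= 1, N_final > N0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate gene trees with tunable rate covariation
#'
#' Each gene g draws a log-normal scaling beta_g and per-branch Gaussian
#' deviations eps on the square-root scale; a branch's length is
#' (beta_g * a_b + eps)^2 with a_b the square root of the master branch
#' length, floored at 0. For each designated covarying pair, the deviations
#' are a shared component with weight rho plus an independent component with
#' weight sqrt(1 - rho^2), so rho = 0 gives independent genes and rho = 1
#' identical deviations.
#'
#' @param config A [sim_config()]. `n_reference_genes` reference genes named
#'   `refNNN` and `n_pairs` focal pairs named `pairK_a`/`pairK_b` are
#'   generated.
#' @return A [gene_tree_set()].
#' @export
simulate_gene_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  master <- ape::unroot(config$master)
  a <- sqrt(master$edge.length)
  nb <- length(a)
  gene_tree <- function(beta, eps) {
    t <- master
    t$edge.length <- pmax(0, beta * a + eps)^2
    t
  }
  trees <- list()
  for (i in seq_len(config$n_reference_genes)) {
    trees[[sprintf("ref%03d", i)]] <- with_local_seed(
      substream_seed(config$seed, i), {
        beta <- stats::rlnorm(1, 0, config$beta_sdlog)
        gene_tree(beta, stats::rnorm(nb, 0, config$sigma))
      })
  }
  rho <- config$rho
  for (k in seq_len(config$n_pairs)) {
    pair <- with_local_seed(substream_seed(config$seed, 10000L + k), {
      z <- stats::rnorm(nb, 0, config$sigma)
      lapply(1:2, function(m) {
        beta <- stats::rlnorm(1, 0, config$beta_sdlog)
        eps <- rho * z +
          sqrt(1 - rho^2) * stats::rnorm(nb, 0, config$sigma)
        gene_tree(beta, eps)
      })
    })
    trees[[sprintf("pair%d_a", k)]] <- pair[[1L]]
    trees[[sprintf("pair%d_b", k)]] <- pair[[2L]]
  }
  gene_tree_set(master, trees)
}

#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Discrete generation-doubling growth from `N0` to about `N_final`: each
#' generation every cell divides; newborn non-mutant cells mutate with
#' probability `mu`, and existing mutant lineages double. The resulting
#' revertant counts are jackpot-skewed (variance far above Poisson), the
#' signature the median-based estimator is designed for.
#'
#' @param config A [sim_config()] (`mu`, `N0`, `N_final`, `n_cultures`).
#' @param strain Strain label for the output table (default "sim").
#' @return A [culture_table()] with one row per culture.
#' @export
simulate_cultures <- function(config, strain = "sim") {
  stopifnot(inherits(config, "sim_config"))
  gens <- round(log2(config$N_final / config$N0))
  if (gens > 60) stop("more than 60 generations requested; overflow guard")
  one <- function(i) with_local_seed(substream_seed(config$seed, 20000L + i), {
    nonmut <- config$N0
    mut <- 0
    for (g in seq_len(gens)) {
      new_mut <- stats::rbinom(1L, nonmut, config$mu)
      mut <- 2 * mut + new_mut
      nonmut <- 2 * nonmut - new_mut
    }
    c(r = mut, N = mut + nonmut)
  })
  res <- t(vapply(seq_len(config$n_cultures), one, numeric(2L)))
  culture_table(data.frame(strain = strain, batch = 1L,
                           revertants = res[, "r"], viable = res[, "N"],
                           stringsAsFactors = FALSE))
}

#' Simulate a tetrad count table
#'
#' TT ~ Binomial(n_tetrads, p_tt), PD = n_tetrads - TT, per genotype.
#'
#' @param config A [sim_config()]; `p_tt` and `n_tetrads` may be vectors
#'   (recycled against `genotypes`).
#' @param genotypes Genotype labels (default "sim").
#' @return A [tetrad_table()].
#' @export
simulate_tetrads <- function(config, genotypes = "sim") {
  stopifnot(inherits(config, "sim_config"))
  k <- length(genotypes)
  p <- rep_len(config$p_tt, k)
  n <- rep_len(config$n_tetrads, k)
  tt <- vapply(seq_len(k), function(i)
    with_local_seed(substream_seed(config$seed, 30000L + i),
                    stats::rbinom(1L, n[i], p[i])), numeric(1L))
  tetrad_table(data.frame(genotype = genotypes, TT = tt, PD = n - tt,
                          stringsAsFactors = FALSE))
}

#' Simulate a two-subfamily alignment with planted specificity columns
#'
#' Background columns share one residue distribution across both groups
#' (majority residue at `background_conservation`, the rest uniform over the
#' other residues). Planted specificity columns use disjoint group-specific
#' majority residues at `specificity_conservation` within each group.
#'
#' @param config A [sim_config()].
#' @return A [subfamily_alignment()] with attribute `spec_columns`, the
#'   planted column indices (the ground truth for recovery tests).
#' @export
simulate_paralog_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nA <- config$n_group_a; nB <- config$n_group_b
  stopifnot(nA >= 4L, nB >= 4L)
  L <- config$aln_length
  n <- nA + nB
  with_local_seed(substream_seed(config$seed, 40000L), {
    spec_cols <- sort(sample.int(L, config$n_specificity_columns))
    m <- matrix(GAP, n, L)
    draw_col <- function(consensus, cons_level, k) {
      hit <- stats::runif(k) < cons_level
      out <- rep(consensus, k)
      others <- setdiff(AA_ALPHABET, consensus)
      out[!hit] <- sample(others, sum(!hit), replace = TRUE)
      out
    }
    for (j in seq_len(L)) {
      if (j %in% spec_cols) {
        res <- sample(AA_ALPHABET, 2L)   # disjoint group consensuses
        m[seq_len(nA), j] <- draw_col(res[1L], config$specificity_conservation, nA)
        m[nA + seq_len(nB), j] <- draw_col(res[2L], config$specificity_conservation, nB)
      } else {
        res <- sample(AA_ALPHABET, 1L)
        m[, j] <- draw_col(res, config$background_conservation, n)
      }
    }
    ids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
    groups <- stats::setNames(rep(c("A", "B"), c(nA, nB)), ids)
    seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), ids)
    aln <- subfamily_alignment(seqs, groups)
    attr(aln, "spec_columns") <- spec_cols
    aln
  })
}
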