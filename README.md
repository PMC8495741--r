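# paralogdiverge

Tools for quantifying **sub-functionalization of paralogous gene families** —
how duplicated genes divided an ancestral function between them. The package
was built around the yeast MutL-homolog (MLH) paralogs, where Pms1 specialized
in DNA mismatch repair (MMR) and Mlh3 in meiotic crossover resolution, and
implements the four quantitative analyses that kind of study needs:

1. **Evolutionary rate covariation (ERC)** — branch lengths of gene/domain
   trees on a shared species topology are normalized into relative
   evolutionary rates, RER(g, b) = sqrt(len(g, b)) − beta(g)·a(b), where a is the
   per-branch mean square-root length of a reference gene panel and beta(g) a
   through-origin least-squares scaling. ERC is the Pearson correlation of two
   genes' Winsorized RER vectors (the two most extreme values per tail clipped
   to the third), with an empirical p-value from a reference-panel null.
2. **Specificity-determining positions** — per-column *sequence harmony*
   (1 − Jensen–Shannon divergence of the two subfamilies' residue
   distributions) and *multi-RELIEF* (nearest-hit/nearest-miss contrast)
   scores; columns with mr > 0.8 and sh < 0.5 are candidates, mapped to
   ungapped residue coordinates and grouped into proximity blocks.
3. **Fluctuation-assay mutation rates** — the method of the median solves
   mu = f / ln(N·mu) for the rate per cell per generation, with
   order-statistic 95% CIs, Mann–Whitney strain comparisons, and
   relative-to-wild-type ratios.
4. **Tetrad crossover classification** — percent tetratype
   (100·TT/(TT+PD)), Pearson chi-squared tests against functional and null
   references, one Benjamini–Hochberg family at 5% FDR, and three-way
   calls {+, −, +/−}.

A first-class **synthetic-data generator** produces gene trees with tunable
rate covariation, Luria–Delbrück culture tables, binomial tetrad draws, and
two-subfamily alignments with planted specificity columns, so the whole
pipeline is testable without external data. See the methods vignette
(`vignettes/paralog-divergence-methods.Rmd`) for models, parameter defaults,
and limitations.

## Worked example

Estimate mutation rates for a simulated wild type and mutator, then classify a
simulated allele's crossover phenotype:

```r
library(paralogdiverge)

cultures <- rbind(
  simulate_cultures(sim_config(seed = 11, mu = 1.0e-7, n_cultures = 24), "WT"),
  simulate_cultures(sim_config(seed = 12, mu = 6.1e-7, n_cultures = 24), "mutator"))
fluctuation_analysis(culture_table(cultures), reference = "WT")
#>    strain  n       mu   ci_low  ci_high relative_to_reference relative_raw
#> 1      WT 24 1.05e-07 8.67e-08 1.24e-07                  1.00         1.00
#> 2 mutator 24 5.41e-07 4.67e-07 7.08e-07                  5.14         5.14
#>   mann_whitney_p_vs_reference
#> 1                    1.00e+00
#> 2                    2.74e-08
```

Both true rates are recovered within their CIs, and the mutator's rate is
5.14× wild type (true ratio 6.1) with a decisive Mann–Whitney p-value.

```r
td <- simulate_tetrads(sim_config(seed = 13, p_tt = c(0.371, 0.183, 0.27),
                                  n_tetrads = c(1023, 1239, 800)),
                       genotypes = c("WT", "mlh3del", "allele1"))
tetrad_calls(td, wt = "WT", null = "mlh3del")[,
  c("genotype", "TT", "PD", "percent_tt", "p_vs_wt", "p_vs_null", "call")]
#>   genotype  TT  PD percent_tt  p_vs_wt p_vs_null call
#> 1  allele1 215 585       26.9 5.17e-05  9.33e-08  +/-
```

The allele planted at 27% tetratype is distinguishable from both the 37.1%
functional and 18.3% null references: an intermediate ("+/−") crossover
phenotype.

ERC on simulated covarying gene pairs (rho = 0.9) against a 60-gene reference
panel:

```r
cfg <- sim_config(seed = 21, n_reference_genes = 60, n_pairs = 2, rho = 0.9)
gt <- simulate_gene_trees(cfg)
# ... estimate_normalization() on the reference genes, compute_rer_set(),
# erc_analysis(); see the vignette for the full listing
#>    gene_a  gene_b     erc n_branches       p null_size
#> 1 pair1_a pair1_b  0.7418         33 0.00826       120
#> 6 pair2_a pair2_b  0.8277         33 0.00826       120
```

The two planted covarying pairs show high ERC at the smallest attainable
empirical p; the four mixed (independent) combinations stay near zero.

A shell-style front-end wrapping the same functions ships at
`inst/cli/paralogdiverge.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/paralogdiverge.R", package="paralogdiverge"))')" demo --seed 7 --out demo_out/
```

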