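---
title: "Methods: quantifying paralog sub-functionalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying paralog sub-functionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiverge)
```

`paralogdiverge` implements four quantitative analyses used to dissect how
duplicated MutL-homolog (MLH) genes divided an ancestral function between
mismatch repair (MMR) and meiotic crossing over: evolutionary rate covariation
(ERC) between gene and domain trees, discovery of specificity-determining
alignment positions between two paralog subfamilies, fluctuation-assay
mutation-rate estimation, and tetrad-based crossover classification. This
vignette explains each model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Relative evolutionary rates and ERC

### Model

All gene and domain trees are assumed to share one master species topology
(branch identity is by leaf bipartition, so rooting is irrelevant; taxa
missing from a gene prune the master, and branches that fuse during pruning
are treated as missing rather than imputed). For a reference panel of genes,
the *normalization vector* is the per-branch mean of square-root-transformed
branch lengths,

$$a_b = \mathrm{mean}_g \sqrt{\ell_{g,b}},$$

kept only on branches carried by at least `min_support` (default 5) reference
genes. The square root is a variance-stabilizing transform for branch lengths,
whose sampling variance grows with their magnitude. Each gene is then
projected onto the normalization vector by least squares through the origin,

$$\hat\beta_g = \frac{\sum_b \sqrt{\ell_{g,b}}\, a_b}{\sum_b a_b^2},
\qquad \mathrm{RER}_{g,b} = \sqrt{\ell_{g,b}} - \hat\beta_g a_b,$$

so a gene's relative evolutionary rates (RERs) are the branch-specific
deviations from its own genome-calibrated expectation. Through-origin fitting
(no intercept, no weighting) is a deliberate choice: multiplying a gene's raw
branch lengths by $c$ scales its whole residual vector by $\sqrt c$, which
leaves every downstream Pearson correlation unchanged — the package asserts
this invariance to 1e-10. Genes sharing fewer than `min_branches` (default 10)
branches with the normalization vector are rejected rather than scored.

ERC between two genes is the Pearson correlation of their Winsorized RER
vectors over shared branches. Winsorization clips, per tail, the two most
extreme values (by rank, stable under ties) to the third order statistic of
that tail; vectors with fewer than five finite or three distinct values pass
through unchanged. This guards the correlation against single long-branch
outliers while never re-ordering elements; in simulation it never flips the
sign of correlations above 0.9.

### Empirical p-values

The construction of the empirical null is a design decision of this package:
the null distribution for a focal pair is the set of ERC values of *each*
focal gene against *every* member of the reference panel (pooled over both
members), and

$$p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{observed}\}}{1 + \#\mathrm{null}},$$

with the add-one correction preventing $p = 0$. A panel below 50 genes
triggers a warning rather than an error. On 500 simulated independent pairs
this yields a type-I error close to the nominal 0.05 (the acceptance script
recomputes it, and the test suite requires 0.05 ± 0.02).

### What the 18-taxon scale implies

The packaged master tree has 18 taxa and therefore 33 unrooted branches. For
*independent* 33-point profiles the expected magnitude of a Pearson
correlation is $\sqrt{2/\pi(n-1)} \approx 0.14$, so individual null ERC values
of ±0.2 are unremarkable at this scale; calibration must be judged by the
empirical p-values, which is why the package reports them. Null ERC is
*centered* at zero (|mean| < 0.1 over 500 pairs), but its mean absolute value
is necessarily about 0.14.

## Specificity-determining positions

Two per-column scores compare the residue distributions of two labeled
subfamilies (A, e.g. Mlh3-like; B, e.g. Pms1-like). Gaps and ambiguity codes
(B, Z, X) are excluded from distributions, and a column is masked when either
group is more than 50% gapped.

**Sequence harmony (sh)** is $1 - \mathrm{JSD}(p_A, p_B)$ with base-2
logarithms and equal weights, where $p_A, p_B$ are the groups' residue
frequencies. Identical distributions score 1; disjoint ones score 0. Low sh
flags columns whose residue usage differs between subfamilies.

**Multi-RELIEF (mr)** is a two-group RELIEF weight estimated by Monte Carlo:
each of `iterations` (default 10,000) draws samples a sequence uniformly,
finds its nearest *hit* (same group) and nearest *miss* (other group) by
similarity over unmasked columns — ties broken uniformly at random — and adds,
per column, (miss differs) − (hit differs). Weights are sums divided by
iterations, hence in [−1, 1]; a column separating the groups perfectly scores
1, a constant column 0. The seed is mandatory and recorded. The exact formulas
behind the original web service are not published; this implementation is
checked against exhaustive enumeration of all (sample, hit, miss) outcomes on
small alignments and satisfies the score ranges and cutoff directions used in
practice, but equivalence with the original server is not claimed.

Candidate positions satisfy mr > 0.8 **and** sh < 0.5 (the published working
cutoffs, both configurable). Positions map to 1-based ungapped residue numbers
of a chosen reference sequence in each subfamily, and are grouped into blocks
as maximal runs with successive gaps of at most `block_gap = 15` residues — a
linear-proximity stand-in for grouping by 3D distance on a structure, adequate
for contiguous clusters but blind to positions adjacent only in the fold.

A simplified conserved-column filter (gap fraction at most `max_gap_frac`, no
gappy neighbor, majority-residue frequency at least `min_conservation`) is
provided for pre-filtering noisy alignments; it is a stand-in for heavier
alignment-trimming tools, not a reimplementation of them.

### Recovery behavior worth knowing

The generator plants specificity columns with within-group conservation 0.9.
At that conservation, a planted column's *expected* mr is about 0.84: even a
perfectly chosen hit differs at the column with probability ≈ 0.1, and the
realized deviant fraction in groups of 29 and 34 sequences fluctuates by ±5%.
Roughly one planted column in four therefore falls below the 0.8 cutoff in any
given draw, while false positives are essentially absent in simulation (the
acceptance script reports both counts). Users should read the cutoff pair as
high-precision /
moderate-recall: positions that pass are trustworthy; positions that fail may
still be real.

## Fluctuation-assay mutation rates

The method of the median solves Drake's equation

$$\mu = \frac{f}{\ln(N\mu)}$$

where $f$ is the median per-culture mutant frequency ($f_i = r_i / N_i$,
median taken over cultures — the median-of-frequencies convention) and $N$ the
median viable count per culture ($N$ must be total viable cells; revertant
counts cannot satisfy the equation dimensionally). The root with $N\mu > 1$ is
found by bracketed bisection plus a fixed-point polish to relative tolerance
1e-12; the forward/inverse round trip is exact to 1e-8 across
$\mu \in [10^{-9}, 10^{-3}]$, $N \in [10^6, 10^{10}]$. Zero median frequency
reports rate 0 with a flag; $0 < f \le e/N$ has no meaningful root and errors.

95% confidence intervals use nonparametric order-statistic ranks on the
per-culture frequencies — lower rank $\lfloor (n - 1.96\sqrt n)/2 \rfloor$,
upper rank $\lceil 1 + (n + 1.96\sqrt n)/2 \rceil$, clamped to $[1, n]$,
undefined below $n = 6$ — and the bracketing frequencies are mapped to rates
through the same equation at the median $N$ (monotone, so the interval always
contains the point estimate). This CI is approximate by construction; over 100
simulated experiments at $\mu = 10^{-7}$ with 30 cultures its coverage of the
true rate lands above 0.9, and the package documents 0.85 as the supported
lower bound. Strain comparisons use the two-sided Mann–Whitney U test: exact
when min(n) ≤ 8 with no ties, otherwise the normal approximation with tie and
continuity corrections (the test suite checks that the corrected approximation
tracks the exact branch within 0.02 at n = 8). Rates relative to
a reference strain are reported raw and rounded to 3 significant figures (ties
half to even).

## Tetrad crossover classification

Crossover activity in a two-marker interval is $100\,TT/(TT+PD)$ (percent
tetratype). Each allele is compared with a functional reference and a null
reference by the Pearson chi-squared test on the 2×2 count table, 1 df,
without Yates continuity correction (the correction is available behind a
flag). All p-values — both comparisons for every allele — form a single
Benjamini–Hochberg family at 5% FDR: the step-up rule finds the largest $k$
with $p_{(k)} \le k q / m$ and reports $p_{(k)}$ as the cutoff, which is
data-dependent by construction (a published cutoff for one particular family
cannot be reproduced without that family's raw p-values). Calls follow the
significance pattern: different from null only → "+" (functional), different
from functional only → "−" (null-like), different from both → "+/−"
(intermediate), different from neither → "indeterminate" (logged; a sign of
underpowered counts). Note that an allele truly *at* a reference frequency
still has a ~5% chance of a spurious "+/−" call — that is the accepted FDR,
not a defect. Map distances are deliberately not computed; the assay scores
TT vs PD only.

## The synthetic-data generator

Every analysis can be exercised on generated data with the structure it
assumes:

* **Gene trees** — branch lengths $(\beta_g a_b + \varepsilon_{g,b})^2$ on the
  square-root scale with log-normal $\beta_g$ (sdlog 0.3) and Gaussian
  branch deviations (sd 0.05), floored at zero; covarying pairs share their
  deviation vector with weight $\rho$ and keep an independent component with
  weight $\sqrt{1-\rho^2}$. The 18-taxon master tree is a fixed fungal panel
  with arbitrary but fixed branch lengths (the real species trees behind the
  original analysis are not publicly deposited).
* **Fluctuation cultures** — discrete generation doubling from $N_0 = 10^3$ to
  about $2\times10^8$ cells (guarded at 60 generations): newborn non-mutants
  mutate with probability $\mu$, mutant lineages double. Transparent, and it
  reproduces the diagnostic jackpot skew (variance far above Poisson); it is
  not a continuous-time filtered-Poisson model, so extreme-tail quantiles are
  approximate. Default 30 cultures, matching the 15–44 used in practice.
* **Tetrads** — TT ~ Binomial($n$, $p_{TT}$); the reference conditions are
  $p_{TT} = 0.371$ (functional) and $0.183$ (null) at $n \approx$ 1000–1250.
* **Alignments** — background columns share one majority residue at
  conservation 0.7 across both groups (a realistic level for alignments that
  have passed conserved-column filtering); planted specificity columns use
  disjoint group majorities at within-group conservation 0.9. Group sizes
  default to 29 and 34, the Mlh3/Pms1 panel sizes. Truth columns are returned
  for recovery checks. The generator does not simulate indels, site-rate
  heterogeneity, or phylogenetic correlation among sequences, so passing
  recovery tests demonstrates score behavior under idealized group structure,
  not performance on real alignments.

All generators derive per-unit sub-streams from one master seed, so outputs
are byte-reproducible and stable when unrelated counts change.

## Problem sizes and runtime

The test suite and the acceptance script use desk-scale sizes chosen as
adequate for the properties they check: 500 simulated pairs for null ERC
calibration against a 150-gene reference panel, 100 replicates each for
fluctuation recovery/coverage and tetrad call concordance, 10,000 multi-RELIEF
iterations on alignments of 63 sequences × 300 columns. The full suite runs in
about a minute on one core.

## Known limitations

* The RER normalization reproduces the cited approach's behavior with one
  tunable transform, but the exact modifications used upstream are
  unpublished; whether an intercept or weighting was used there is unknown.
* The empirical-p null construction (reference-panel pooling, add-one rule)
  is this package's own; published empirical p-values built differently will
  not match numerically.
* The order-statistic CI for fluctuation rates is approximate; coverage
  somewhat below the nominal 95% is expected and observed in simulation.
* Block formation is linear; structurally adjacent but sequence-distant
  positions will not merge into one block.
* The BH family composition (which comparisons enter one family) changes the
  cutoff; the package fixes one convention (all allele-vs-reference tests
  together) and exposes `q`.
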