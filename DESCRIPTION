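Package: paralogdiverge
Title: Quantifying Sub-Functionalization of Paralogous Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the functional divergence of paralogous
    protein families, built around four analyses used to study the yeast
    MutL-homolog (MLH) mismatch-repair/crossover paralogs: evolutionary rate
    covariation (ERC) from relative evolutionary rates computed on gene and
    domain trees; discovery of specificity-determining alignment positions
    between two paralog subfamilies using sequence-harmony and multi-RELIEF
    scores; Luria-Delbruck fluctuation-assay mutation-rate estimation by the
    method of the median with nonparametric confidence intervals; and
    tetrad-based meiotic crossover classification with Benjamini-Hochberg
    false-discovery-rate control. A synthetic-data generator reproduces the
    statistical structure each analysis assumes, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
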