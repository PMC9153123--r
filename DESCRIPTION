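Package: cubshift
Title: Quantifying Shifts in Natural Selection on Synonymous Codon Usage
    Between Protein Regions
Version: 0.1.0
Authors@R:
    person("cubshift", "maintainers", email = "cubshift@example.org",
           role = c("aut", "cre"))
Description: Population-genetics analysis of codon usage bias between
    protein regions (secondary structures, intrinsically disordered
    regions, structure termini). Implements the selection-mutation-drift
    multinomial codon model in which the probability of a synonymous
    codon depends on mutation bias (delta M), natural selection
    (delta eta) scaled by gene expression (phi), fitted per region by
    adaptive random-walk Metropolis MCMC with model comparison by the
    Deviance Information Criterion. Region comparisons use errors-in-
    variables (Deming) regression, codon-specific 95% posterior-interval
    shift calls, Spearman correlation and an exact binomial false-
    positive audit. Includes a forward simulator of annotated coding
    sequences (heterogeneous-selection regions with sign-flipped
    selection at a chosen fraction of sites; replicate uniform-selection
    null genomes) and a position-wise Fisher's exact odds-ratio analysis
    with simulated null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
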