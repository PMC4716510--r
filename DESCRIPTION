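Package: kindyad
Title: Dyadic Relatedness Estimation and Kin Effects on Male Residence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of pairwise genetic relatedness
    from codominant microsatellite genotypes via the three-state
    identity-by-descent dyad likelihood, with a Queller-Goodnight moment
    estimator for comparison; simulation-based power of relationship
    inference; empirical and simulation-based cutoff rules classifying
    dyads as related or unrelated, with validation accounting and
    Mendelian parent-offspring checks; and downstream survival-style
    analyses of male residence time and high-rank tenure with a cluster
    bootstrap over individuals. Includes GenePop and CSV genotype input
    and output, marker quality control (Monte-Carlo Hardy-Weinberg exact
    test, Bonferroni correction), and synthetic-data generators for
    allele frequencies, pedigreed genotypes under paternity skew, and
    residence records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
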