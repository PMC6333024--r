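Package: gsbreedr
Title: Genomic Selection Analysis for Perennial Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for genomic selection in small
    perennial breeding populations of backcross and F2 families. Provides a
    gene-dropping simulator for pedigreed SNP panels and multi-year trait
    records, SNP quality control (call rate, minor allele frequency,
    invariant-marker removal), EM-REML variance component estimation with
    BLUP from Henderson's mixed-model equations, ridge (G-BLUP) and kernel
    solvers for marker effects and genomic breeding values with an optional
    Gibbs sampler, k-fold cross-validation of predictive capacity and bias,
    and the derived breeding-design statistics: selective accuracy, effective
    number of QTL, required population size, marker-density response, and
    selective efficiency per unit time.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
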