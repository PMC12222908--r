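Package: hlaDiversity
Title: Population Diversity Analysis of Class I HLA Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising class I HLA (HLA-A, -B, -C) diversity in
    multi-population genotype cohorts typed at two-field resolution. Implements
    allele frequency estimation by direct counting, haplotype frequency
    estimation by expectation-maximisation with progressive locus insertion,
    exact Hardy-Weinberg testing by Markov chain Monte Carlo, the
    Ewens-Watterson homozygosity test of neutrality under the conditional
    Ewens sampling formula, asymmetric linkage disequilibrium, Shannon and
    Gini-Simpson alpha diversity, Hellinger-distance beta diversity and
    similarity matrices, rarefaction and extrapolation of allelic richness
    with bootstrap confidence intervals, classical multidimensional scaling
    of haplotype-frequency profiles, within-locus allele co-occurrence
    tables, and a synthetic cohort generator with controlled allele spectra,
    linkage disequilibrium, inbreeding and genotyping error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
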