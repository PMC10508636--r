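Package: ascbias
Title: SNP Ascertainment Bias in f-Statistics and Admixture Graph Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based study of how non-random SNP ascertainment biases
    f-statistics and admixture graph fitting. Provides polarized genotype
    matrices with EIGENSTRAT/VCF input, coalescent simulation of demographic
    histories (case-study archaic/modern human models, random admixture
    graphs, bottlenecked four-taxon trees) through msprime, a library of
    ascertainment schemes (Human Origins style heterozygosity panels, minor
    allele frequency thresholds, archaic polymorphism, mutation-class and
    random thinning), f2/f3/f4 statistics and Hudson FST with weighted block
    jackknife errors, exhaustive admixture graph topology enumeration and
    least-squares graph fitting (log-likelihood score and worst f4 residual),
    and the bias/power metrics used to classify ascertainment schemes
    (flipped-verdict fractions, residual SE of Z-score trends, thinned
    replicate null classifiers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    arrow,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
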