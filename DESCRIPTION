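Package: panblup
Title: Pan-Genome Relationship Kernels, REML Mixed Models and Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction and heritability estimation from three layers of
    pan-genome variation in microbial populations: biallelic SNP genotypes,
    open-reading-frame (ORF) presence/absence, and ORF copy numbers. Builds the
    corresponding relationship kernels (G, O, C), fits single- and two-kernel
    linear mixed models by average-information REML (GBLUP, OBLUP, CBLUP,
    GOBLUP, GCBLUP), computes kernel-based heritabilities, runs Bayes A/B
    whole-genome regression by Gibbs sampling, measures cross-validated
    predictive ability, and fits the asymptotic accuracy curve
    r = w*sqrt(n*h2/(n*h2 + Me)) to training-size series. Includes population
    structure summaries (PCA, gene distances, neighbor-joining trees), quality
    filters for SNP/ORF/copy-number matrices, and a synthetic pan-genome
    simulator with known genetic architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, ape, vcfR, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
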