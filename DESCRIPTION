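Package: congenicScope
Title: Characterizing Congenic Strain Introgressed Segments and the
    Molecular Evolution of Candidate Signal Genes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the donor chromosome segment carried by
    a backcross-derived congenic strain and for triaging and analysing the
    genes it contains. Provides the analytic expectation and a Monte-Carlo
    simulator for the length of donor chromatin retained around a selected
    locus after N backcross generations; inference of the introgressed
    interval from strain SNP haplotypes with identity-by-descent masking and
    a subspecies-ancestry based "functional" segment size; staged
    expression/localization/divergence/proteome filters producing a candidate
    signal-gene set with per-gene provenance; codon-aware counting of
    synonymous and nonsynonymous substitutions with Grantham
    conservative/radical classification; neighbor-joining gene trees and
    congruence testing against a species tree containing a polytomy; and a
    Goldman-Yang codon site-model engine (M8 vs M8A likelihood-ratio test
    with Bayes-empirical-Bayes detection of positively selected sites).
    Synthetic-data generators with known ground truth cover every input
    class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceMatching, Software
RoxygenNote: 7.3.3
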