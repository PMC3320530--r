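Package: citrusnp
Title: SNP-Array Population Genetics for Stratified Clonal Gene Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diploid biallelic SNP-array genotypes in
    highly stratified, clonally propagated gene pools such as cultivated
    Citrus. Classifies markers from F1-progeny segregation including
    null-allele and duplicated-locus models, computes diversity statistics
    (Ho, He, genotypic diversity) and Weir-Cockerham F-statistics,
    simple-matching dissimilarities with bootstrap neighbor-joining trees,
    PCA with supplementary-individual projection, composite linkage
    disequilibrium, trio parentage-compatibility scoring and comparative
    mappability matrices. Ships a synthetic stratified-gene-pool generator
    (Balding-Nichols divergence, fixed-heterozygosity hybrids, taxon-specific
    null-allele rates, single-genotype marker ascertainment and an F1
    progeny) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
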