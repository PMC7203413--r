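Package: tetrabc
Title: Transmission Genetics of Autotetraploid Backcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of polysomic inheritance in BC1F1 populations derived
    from crosses between a tetraploid inbred recurrent parent and a tetraploid
    interspecific F1 hybrid, as arises in Sorghum bicolor x Sorghum halepense
    crosses genotyped by sequencing (GBS). Provides closed-form and
    enumeration-based gamete dosage distributions for simplex and duplex
    markers under random chromosome, random chromatid, and maximum equational
    segregation with double reduction; a meiosis and GBS read simulator
    emitting VCF with diploid-style PL fields; PL-based genotype calling to
    presence/absence (AA/AB) matrices; linkage grouping, 1-cM binning, de novo
    marker ordering and error-aware map estimation with the Kosambi function;
    chi-square segregation-ratio tests, linkage-group enrichment
    classification and segregation-distortion region detection; and
    classification of hybrid alleles by progenitor origin with detection of
    runs of consecutive progenitor-specific alleles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
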