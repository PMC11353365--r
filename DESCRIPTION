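Package: laivr
Title: Local Ancestry Inference from Population-Specific SNPs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Local ancestry inference for phased admixed genomes using
    population-specific single-nucleotide polymorphisms. Screens reference
    cohorts for SNPs whose minor allele is confined to one reference
    population, computes local ancestry information vectors (moment
    estimators of local ancestral proportions) in a sliding window along
    each haplotype, calls per-locus ancestry under confidence thresholds and
    merges the calls into ancestry segments. Ships a mosaic admixture
    simulator with known truth tracts plus consistency-rate and
    uncalled-rate metrics, so callers can be validated end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
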