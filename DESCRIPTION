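Package: cendrift
Title: Centromere Chromatin Domains from Single-Molecule Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of centromere chromatin domains from
    single-molecule modification data (DiMeLo-seq style 6mA and endogenous
    5mCG). Calls centromere dip regions (CDRs) as valleys in 5mCG tracks over
    active alpha-satellite higher-order repeats, expands CENP-A/CENP-C domain
    boundaries by seeded expansion from CDR annotations, classifies newly
    formed CDRs, computes per-molecule 6mA densities with IgG normalization,
    measures CENP-A domain drift from binned enrichment profiles, and builds
    length-normalized meta-region matrices and aggregate profiles. Includes a
    seeded synthetic centromere-epigenome generator with recorded ground truth
    so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
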