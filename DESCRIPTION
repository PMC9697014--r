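Package: kaspqc
Title: Quality Control and Diversity Analysis for Low-Density SNP
    Fingerprinting of Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and using low-density reference SNP
    fingerprints of inbred germplasm collections genotyped with
    KASP-style biallelic markers.  Covers per-marker quality statistics
    (minor allele frequency, heterozygosity, missing rate, polymorphic
    information content) and the marker filter cascade; replicate-based
    seed-purity and genetic-identity checks; consensus fingerprint
    construction from biological replicates with mislabel resolution;
    identity-by-state genetic distances, distance-distribution summaries,
    principal component analysis and neighbor-joining trees; and a fully
    parameterised synthetic genotype-panel generator with ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
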