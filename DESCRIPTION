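Package: domescan
Title: Selection-Signature Scans and Colocalization Statistics for
    Domestication Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic tool kit for detecting and interpreting
    domestication signatures in inbreeding crops. Implements windowed
    wild/cultivated expected-heterozygosity ratio scans with percentile
    signature calling, Hudson and Weir-Cockerham F_ST, composite linkage
    disequilibrium (r2) and its decay extent, a two-locus common-haplotype
    sharing ratio between populations, an exact hypergeometric test for
    overlap between selection signals and QTL likelihood intervals on a
    genetic-bin grid, LD-adjusted genome-wide significance thresholds,
    genetic-to-physical interval anchoring, and RGB to CIE-L*a*b* seed-color
    phenotyping. Includes a seeded founder-block Balding-Nichols simulator
    that plants selective sweeps with recorded truth, plus readers and
    writers for VCF, dosage TSV, genetic-map and BED formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
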