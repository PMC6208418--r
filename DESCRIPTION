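Package: linkscaf
Title: Linkage Maps and Scaffold Anchoring from Low-Coverage Hybrid Crosses
Version: 0.1.0
Authors@R: person("Linkscaf", "Developers", email = "linkscaf@example.org",
    role = c("aut", "cre"))
Description: Builds ultrahigh-density genetic linkage maps from very
    low-coverage (about 1-2x) whole-genome genotypes of hybrid offspring,
    and uses them to order, orient and concatenate draft-assembly scaffolds
    into chromosome-scale linkage groups. Because every offspring read can
    be attributed to one of two divergent parental genomes, a single read at
    a site heterozygous in the focal parent identifies the transmitted
    haplotype, so each parent can be mapped as if it were a panel of double
    haploids. The package provides the marker-filter cascade, rule-based
    per-scaffold phasing with crossover detection, greedy end-phase
    concordance chaining, two-point centimorgan mapping, writers for AGP and
    extended FASTA, and a meiosis simulator that generates genotype data
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
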