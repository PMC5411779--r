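Package: asmeval
Title: Evaluation of Genome Assembly Version Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate a pair of versions of a clone-based genome
    assembly. Classifies each assembly, per base, as collapsed, expanded,
    uniquely aligned or unaligned from reciprocal/nonreciprocal best-hit
    alignment blocks; restricts paired-end read alignments to regions whose
    underlying AGP component is unchanged between versions and classifies
    read-pair movement into a six-way destination taxonomy; validates
    candidate reference-base errors from MAPQ-filtered pileups with
    homozygosity cutoffs and a retain-heterozygous rule; assesses variant-site
    coverage transitions and ambiguous coordinate remapping between versions;
    and ships a deterministic simulator that builds two-version assembly
    pairs with implanted curation events, reads with truth placements, and
    candidate sites with truth genotypes, so every stage can be checked
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
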