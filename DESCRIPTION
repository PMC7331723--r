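Package: rohmapper
Title: Autozygosity Mapping and Recessive Variant Prioritization in
    Consanguineous Pedigrees
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gene discovery in consanguineous families with a
    fully penetrant autosomal recessive disorder. Implements run-of-
    homozygosity (ROH) detection from exome genotype calls (a span of at
    least 25 SNPs with at most two heterozygous calls), intersection of
    ROH across affected siblings, a five-rule exclusion cascade for
    annotated variants (read support, population and in-house frequency,
    population homozygotes, synonymous and non-coding consequences),
    autosomal recessive co-segregation checking with obligate-carrier
    logic, and metacarpophalangeal pattern profiling (age- and sex-
    standardized hand-bone z-scores) for objective brachydactyly
    assessment. A gene-dropping pedigree simulator with Haldane
    recombination generates synthetic families with planted pathogenic
    variants and ground-truth identity-by-descent segments for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'anthropometry.R'
    'variantset.R'
    'genomemap.R'
    'pedigree.R'
    'genedrop.R'
    'emit.R'
    'filters.R'
    'measurements.R'
    'vcf-io.R'
    'plant.R'
    'simulate-family.R'
    'segregation.R'
    'roh.R'
    'pipeline.R'
    'rohmapper-package.R'
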