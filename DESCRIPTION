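Package: mitosig
Title: Somatic Mitochondrial DNA Mutation Signatures, Selection and Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mitochondrial DNA mutations in tumor/normal
    sequencing data. Implements sample-swap and cross-contamination QC on
    homozygous SNP panels, a heteroplasmy-aware somatic variant filter chain
    with read-backed phasing, strand-resolved trinucleotide mutational
    signature extraction with replicative versus transcriptional strand-model
    comparison, context-dependent Poisson dN/dS selection inference by
    maximum likelihood, signature-driven sequence-evolution simulation to
    stationary composition, codon-usage skew statistics, and a Wright-Fisher
    model of heteroplasmy drift to homoplasmy. A synthetic-data generator
    produces circular annotated genomes, variant cohorts, allele-count
    pileups and phasing evidence with the statistical structure the analysis
    assumes, so the full pipeline runs end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
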