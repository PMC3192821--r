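Package: codonfragility
Title: Fragile Codon Usage and Robustness to Nonsense Transcriptional Errors
Version: 1.0.0
Authors@R: person("Codon", "Fragility Maintainers",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies sense codons of the standard genetic code by whether a
    single point mutation can convert them into a stop codon ("fragile"
    codons) and quantifies their usage with the FCU, NFCU, FAU and NFAU
    metrics, which control for amino-acid content and GC composition.
    Provides gene-model handling from FASTA/GFF3 (representative-transcript
    selection, exon-level codon assignment, exon-junction boundary windows,
    exonic splicing enhancer coverage, fraction of optimal codons), a
    Nei-Gojobori (1986) Ka/Ks estimator for selective-constraint binning,
    the comparison statistics used throughout (rank-sum, signed-rank, sign
    test, Spearman correlation with confidence intervals, quartile binning),
    a synthetic gene-model generator with a truth manifest for end-to-end
    validation, and pipeline drivers for intergenic, intragenic, window-based,
    binned and constraint-correlation analyses of fragile codon depletion
    where nonsense-mediated decay is inefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
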