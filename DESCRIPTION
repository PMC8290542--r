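Package: iraQTL
Title: Bin-Marker QTL Mapping and Inconsistent-Rate Fine-Mapping for RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping monogenic (qualitative) traits in
    recombinant inbred line (RIL) populations genotyped by low-coverage sequencing.
    Provides a RIL population simulator (selfing pedigrees, Poisson crossovers,
    genotyping noise), parent-informative variant filtering, sliding-window
    bin-marker genotype calling with recombination-breakpoint resolution, genetic
    map construction via the Kosambi mapping function with RIL recombination
    correction, composite-interval-style LOD scanning with permutation thresholds,
    inconsistent rate analysis (IRA) for narrowing QTL to small physical windows,
    and codon-level variant-effect annotation of candidate genes from GFF3 gene
    models and a genome FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Genetics, GeneticVariability, SNP, Software
RoxygenNote: 7.3.3
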