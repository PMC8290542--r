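# Shared fixture builders. Everything is generated in code at test time.

twoChromConfig <- function(n_rils = 100, length_bp = 3e6, morgans = 0.25,
                           n_variants = 600, seed = 1, missing_rate = 0.3,
                           error_rate = 0.01, het_call_rate = 0.02,
                           selfing_generations = 6,
                           causal = data.frame(chrom = "Chr1", pos = 1.5e6,
                                               trait = "AC",
                                               penetrance = 0.97)) {
  simConfig(chromosomes = data.frame(name = c("Chr1", "Chr2"),
                                     length_bp = rep(length_bp, 2),
                                     length_morgans = rep(morgans, 2)),
            n_variants = rep(n_variants, 2), n_rils = n_rils,
            selfing_generations = selfing_generations,
            missing_rate = missing_rate, error_rate = error_rate,
            het_call_rate = het_call_rate,
            causal_loci = causal, seed = seed)
}

# Hand-rolled genotype object: sites at given positions on one chromosome
# with an explicit call matrix (used by filter/linkage/IRA unit tests).
makeGenotypes <- function(calls, positions = NULL, chrom = "Chr1",
                          chrom_len = NULL,
                          p1 = "HOM_REF", p2 = "HOM_ALT") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(positions)) positions <- seq_len(n) * 1000
  if (is.null(chrom_len)) chrom_len <- max(positions) + 1000
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(positions, width = 1),
    seqinfo = GenomeInfoDb::Seqinfo(chrom, chrom_len))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = rep("A", n), alt = rep("G", n), vtype = rep("SNP", n),
    p1_call = rep(p1, n), p2_call = rep(p2, n))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("S%03d", seq_len(ncol(calls)))
  RilGenotypes(gr, calls)
}

# A gene region with n_genes single-exon CDS genes on one contig; selected
# genes carry parent-differentiating variants with prescribed effects.
# Returns genes (GRangesList), genome, variants, and the expected candidate
# gene ids.
makeGeneRegion <- function(n_genes = 12, seed = 99) {
  set.seed(seed)
  safe <- {
    aa <- Biostrings::GENETIC_CODE
    names(aa[aa != "*" & names(aa) != "ATG"])
  }
  chrom <- "ChrT"
  gene_w <- 300L
  gap <- 9700L
  glen <- n_genes * (gene_w + gap) + 20000L
  seqv <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  grl <- list(); variants <- list(); expected <- character()
  for (i in seq_len(n_genes)) {
    st <- 5001L + (i - 1L) * (gene_w + gap)
    codons <- sample(safe, gene_w / 3, replace = TRUE)
    codons[1] <- "ATG"; codons[length(codons)] <- "TGG"
    if (i == 3L) {       # nonsynonymous target: ATT -> GTT at codon 20
      codons[20] <- "ATT"
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chrom, pos = st + 57L, ref = "A", alt = "G")
      expected <- c(expected, sprintf("gene%02d", i))
    }
    if (i == 7L) {       # synonymous: CTG -> CTA at codon 20 (Leu/Leu)
      codons[20] <- "CTG"
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chrom, pos = st + 59L, ref = "G", alt = "A")
    }
    if (i == 9L) {       # nonsynonymous: ATT -> GTT at codon 40
      codons[40] <- "ATT"
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chrom, pos = st + 117L, ref = "A", alt = "G")
      expected <- c(expected, sprintf("gene%02d", i))
    }
    seqv[st:(st + gene_w - 1L)] <- strsplit(paste(codons, collapse = ""),
                                            "")[[1]]
    g <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(st, st + gene_w - 1L),
                                strand = "+")
    grl[[sprintf("gene%02d", i)]] <- g
  }
  genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome) <- chrom
  list(genes = GenomicRanges::GRangesList(grl), genome = genome,
       variants = do.call(rbind, variants), expected = expected,
       region = GenomicRanges::GRanges(
         chrom, IRanges::IRanges(1, n_genes * (gene_w + gap) + 5000L)))
}
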