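#' Simulate a fully informative parental variant catalog
#'
#' Draws variant positions uniformly (without replacement) along each
#' chromosome and assigns ref/alt alleles so that the two parents are
#' homozygous for different alleles at every site, as required of an
#' effective marker in a biparental RIL design. A configurable fraction of
#' sites is flagged as indels (allele strings of unequal length); the rest
#' are SNPs.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return GRanges with seqlengths set and mcols \code{ref}, \code{alt},
#'   \code{vtype} ("SNP"/"indel"), \code{p1_call}, \code{p2_call}.
#' @export
simulateParents <- function(config) {
  validObject(config)
  ch <- config@chromosomes
  .localSeed(config@seed, {
    parts <- lapply(seq_len(nrow(ch)), function(i) {
      n <- config@n_variants[i]
      L <- ch$length_bp[i]
      if (n < 1) stop("zero variants requested on ", ch$name[i])
      pos <- sort(sample.int(L, n))   # without replacement: no duplicates
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      is_indel <- stats::runif(n) < config@indel_fraction
      if (any(is_indel)) {
        k <- sum(is_indel)
        ins <- stats::runif(k) < 0.5
        extra <- vapply(1 + stats::rpois(k, 2), function(m)
          paste(sample(bases, m, replace = TRUE), collapse = ""), "")
        r <- ref[is_indel]; a <- r
        a[ins]  <- paste0(r[ins], extra[ins])          # insertion
        r[!ins] <- paste0(r[!ins], extra[!ins])        # deletion
        a[!ins] <- ref[is_indel][!ins]
        ref[is_indel] <- r; alt[is_indel] <- a
      }
      ref_is_p1 <- stats::runif(n) < 0.5
      data.frame(chrom = ch$name[i], pos = pos, ref = ref, alt = alt,
                 vtype = ifelse(is_indel, "indel", "SNP"),
                 p1_call = ifelse(ref_is_p1, "HOM_REF", "HOM_ALT"),
                 p2_call = ifelse(ref_is_p1, "HOM_ALT", "HOM_REF"))
    })
    df <- do.call(rbind, parts)
    gr <- GRanges(df$chrom, IRanges(df$pos, width = nchar(df$ref)),
                  seqinfo = Seqinfo(ch$name, ch$length_bp))
    mcols(gr) <- DataFrame(ref = df$ref, alt = df$alt, vtype = df$vtype,
                           p1_call = df$p1_call, p2_call = df$p2_call)
    gr
  })
}

# A haplotype along one chromosome: interior breakpoints (increasing, bp on
# a continuous scale) and parental labels (1/2) of the length(brk)+1 pieces.
.hapValue <- function(h, x) h$lab[findInterval(x, h$brk) + 1L]

.compressHap <- function(brk, lab) {
  if (length(lab) > 1L) {
    keep <- c(lab[-1] != lab[-length(lab)])
    brk <- brk[keep]
    lab <- lab[c(TRUE, keep)]
  }
  list(brk = brk, lab = lab)
}

# One gamete from a (possibly recombinant) diploid: crossover count is
# Poisson(genetic length in Morgans), positions uniform in bp, no
# interference, random start strand.
.gamete <- function(h1, h2, morgans, length_bp) {
  k <- stats::rpois(1L, morgans)
  if (k == 0L) return(if (stats::runif(1) < 0.5) h1 else h2)
  xo <- sort(stats::runif(k, 0, length_bp))
  allb <- sort(unique(c(xo, h1$brk, h2$brk)))
  mid <- (c(0, allb) + c(allb, length_bp)) / 2
  from1 <- (findInterval(mid, xo) + (stats::runif(1) < 0.5)) %% 2 == 0
  lab <- ifelse(from1, .hapValue(h1, mid), .hapValue(h2, mid))
  .compressHap(allb, lab)
}

# Diploid genotype as a step function: breakpoints + codes 0/1/2.
.diploSegments <- function(h1, h2, length_bp) {
  allb <- sort(unique(c(h1$brk, h2$brk)))
  mid <- (c(0, allb) + c(allb, length_bp)) / 2
  g1 <- .hapValue(h1, mid); g2 <- .hapValue(h2, mid)
  code <- ifelse(g1 == g2, ifelse(g1 == 1L, GT_P1, GT_P2), GT_HET)
  .compressHap(allb, code)
}

#' Simulate RIL genotypes by recurrent selfing
#'
#' Runs a single-seed-descent pedigree per line: starting from the F1
#' heterozygote, each generation selfs (two independent gametes from the
#' same plant) for \code{selfing_generations} rounds. Crossovers per
#' meiosis are Poisson with mean equal to the chromosome's genetic length
#' in Morgans, placed uniformly in bp, without interference. Residual
#' heterozygosity therefore decays as (1/2)^g.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param catalog variant catalog from \code{\link{simulateParents}}.
#' @return list with \code{genotypes} (a \linkS4class{RilGenotypes} of
#'   true, noise-free calls) and \code{truth} (segments, crossovers and
#'   causal genotypes per RIL).
#' @export
simulateRils <- function(config, catalog) {
  validObject(config)
  ch <- config@chromosomes
  n <- config@n_rils
  g <- config@selfing_generations
  samples <- sprintf("RIL%04d", seq_len(n))
  chr_of <- as.character(seqnames(catalog))
  pos_of <- start(catalog)

  .localSeed(config@seed + 1L, {
    calls <- matrix(NA_integer_, nrow = length(catalog), ncol = n,
                    dimnames = list(NULL, samples))
    seg_list <- vector("list", n * nrow(ch)); xo_list <- seg_list
    causal <- config@causal_loci
    causal_geno <- matrix(NA_integer_, nrow = n, ncol = nrow(causal),
                          dimnames = list(samples, causal$trait))
    k <- 0L
    for (ril in seq_len(n)) {
      for (ci in seq_len(nrow(ch))) {
        L <- ch$length_bp[ci]; M <- ch$length_morgans[ci]
        h1 <- list(brk = numeric(), lab = 1L)
        h2 <- list(brk = numeric(), lab = 2L)
        for (gen in seq_len(g)) {
          n1 <- .gamete(h1, h2, M, L)
          n2 <- .gamete(h1, h2, M, L)
          h1 <- n1; h2 <- n2
        }
        dip <- .diploSegments(h1, h2, L)
        idx <- which(chr_of == ch$name[ci])
        if (length(idx))
          calls[idx, ril] <- dip$lab[findInterval(pos_of[idx], dip$brk) + 1L]
        ends <- floor(c(dip$brk, L))
        starts <- c(1, head(ends, -1) + 1)
        keep <- ends >= starts
        k <- k + 1L
        seg_list[[k]] <- data.frame(ril = samples[ril], chrom = ch$name[ci],
                                    start = starts[keep], end = ends[keep],
                                    genotype = dip$lab[keep])
        if (length(dip$brk))
          xo_list[[k]] <- data.frame(ril = samples[ril], chrom = ch$name[ci],
                                     pos = dip$brk)
        ci_causal <- which(causal$chrom == ch$name[ci])
        for (j in ci_causal)
          causal_geno[ril, j] <- dip$lab[findInterval(causal$pos[j], dip$brk) + 1L]
      }
    }
    truth <- list(
      segments = do.call(rbind, seg_list[!vapply(seg_list, is.null, TRUE)]),
      crossovers = if (any(!vapply(xo_list, is.null, TRUE)))
        do.call(rbind, xo_list[!vapply(xo_list, is.null, TRUE)])
      else data.frame(ril = character(), chrom = character(), pos = numeric()),
      causal_geno = causal_geno,
      causal_loci = causal)
    list(genotypes = RilGenotypes(catalog, calls, samples), truth = truth)
  })
}

#' Overlay genotyping noise on true calls
#'
#' Applies, in this fixed order and independently per call: (1) set MISSING
#' with \code{missing_rate}; (2) flip surviving homozygous calls to the
#' other parent with \code{error_rate}; (3) miscall surviving homozygous
#' calls heterozygous with \code{het_call_rate}. True heterozygous calls
#' are only subject to missingness.
#'
#' @param genotypes \linkS4class{RilGenotypes} of true calls.
#' @param config a \linkS4class{SimConfig}.
#' @return \linkS4class{RilGenotypes} of observed calls.
#' @export
observeGenotypes <- function(genotypes, config) {
  v <- genoCalls(genotypes)
  .localSeed(config@seed + 2L, {
    u_miss <- matrix(stats::runif(length(v)), nrow(v))
    v[u_miss < config@missing_rate] <- NA_integer_
    hom <- !is.na(v) & v != GT_HET
    u_err <- matrix(stats::runif(length(v)), nrow(v))
    flip <- hom & u_err < config@error_rate
    v[flip] <- 2L - v[flip]
    hom <- !is.na(v) & v != GT_HET
    u_het <- matrix(stats::runif(length(v)), nrow(v))
    v[hom & u_het < config@het_call_rate] <- GT_HET
    RilGenotypes(rowRanges(genotypes), v, colnames(v))
  })
}

#' Assign binary phenotypes from causal genotypes
#'
#' Each trait is monogenic: lines homozygous for the P1 allele at the
#' causal locus show the P1-parent phenotype (coded 0), lines carrying the
#' P2 allele (homozygous or residual heterozygotes) show the P2-parent
#' phenotype (coded 1). In every environment, independently, the phenotype
#' is recorded correctly with probability \code{penetrance} and flipped
#' otherwise, so replicate environments share the causal genotype and
#' their correlation approaches 1 as penetrance approaches 1.
#'
#' @param truth truth record from \code{\link{simulateRils}}.
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with columns \code{sample}, \code{trait},
#'   \code{environment}, \code{value}.
#' @export
assignPhenotypes <- function(truth, config) {
  causal <- truth$causal_loci
  if (nrow(causal) == 0L) stop("no causal loci defined in the configuration")
  ch <- config@chromosomes
  lim <- ch$length_bp[match(causal$chrom, ch$name)]
  if (anyNA(lim) || any(causal$pos < 1 | causal$pos > lim))
    stop("causal locus outside the simulated catalog")
  samples <- rownames(truth$causal_geno)
  .localSeed(config@seed + 3L, {
    out <- list()
    for (j in seq_len(nrow(causal))) {
      base <- ifelse(truth$causal_geno[, j] == GT_P1, 0L, 1L)
      for (env in config@environments) {
        flip <- stats::runif(length(base)) > causal$penetrance[j]
        out[[length(out) + 1L]] <- data.frame(
          sample = samples, trait = causal$trait[j], environment = env,
          value = ifelse(flip, 1L - base, base))
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a complete RIL mapping study
#'
#' Convenience wrapper chaining \code{\link{simulateParents}},
#' \code{\link{simulateRils}}, \code{\link{observeGenotypes}} and
#' \code{\link{assignPhenotypes}}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list(catalog, truth, true_genotypes, genotypes, phenotypes).
#' @export
simulateStudy <- function(config) {
  catalog <- simulateParents(config)
  sim <- simulateRils(config, catalog)
  obs <- observeGenotypes(sim$genotypes, config)
  ph <- if (nrow(config@causal_loci)) assignPhenotypes(sim$truth, config) else NULL
  list(catalog = catalog, truth = sim$truth, true_genotypes = sim$genotypes,
       genotypes = obs, phenotypes = ph)
}

# ---- annotation fixtures ---------------------------------------------------

.CODONS_SAFE <- {
  aa <- Biostrings::GENETIC_CODE
  names(aa[aa != "*" & !names(aa) %in% c("ATG")])
}

#' Build a synthetic gene fixture for the annotator
#'
#' Constructs a three-exon protein-coding gene (CDS lengths 100 + 100 + 121
#' bp = 321 bp, 107 codons) embedded in a random genome sequence, with
#' codon 90 fixed to ATT (isoleucine) so that the spliced-CDS base 268 is
#' its first position: an A-to-G substitution there yields GTT (valine), a
#' nonsynonymous change. Works on either strand; on the minus strand the
#' genomic coordinates mirror the plus-strand layout.
#'
#' @param strand "+" or "-".
#' @param chrom chromosome name of the fixture contig.
#' @param seed RNG seed for the filler sequence.
#' @return list with \code{genome} (DNAStringSet), \code{genes}
#'   (GRangesList of CDS in transcription order), \code{variant}
#'   (chrom/pos/ref/alt of the codon-90 substitution in genomic
#'   coordinates) and \code{cds_offset} (= 268).
#' @export
simulateGeneFixture <- function(strand = "+", chrom = "ChrF", seed = 1L) {
  .localSeed(seed, {
    exon_w <- c(100L, 100L, 121L)          # 321 bp CDS, 107 codons
    n_codons <- sum(exon_w) / 3
    codons <- sample(.CODONS_SAFE, n_codons, replace = TRUE)
    codons[1] <- "ATG"; codons[n_codons] <- "TGG"
    codons[90] <- "ATT"
    cds <- paste(codons, collapse = "")
    stopifnot(substr(cds, 268, 270) == "ATT")
    glen <- 700L
    seqv <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    # genomic exon blocks left-to-right; on the minus strand the mRNA's
    # first exon is the rightmost block
    block_w <- if (strand == "+") exon_w else rev(exon_w)
    block_start <- c(51L, 51L + block_w[1] + 100L,
                     51L + block_w[1] + block_w[2] + 200L)
    block_end <- block_start + block_w - 1L
    tx_order <- if (strand == "+") 1:3 else 3:1   # blocks in mRNA order
    off <- 0L
    for (j in seq_along(tx_order)) {
      b <- tx_order[j]
      piece <- substr(cds, off + 1, off + exon_w[j])
      if (strand == "-")
        piece <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(piece)))
      seqv[block_start[b]:block_end[b]] <- strsplit(piece, "")[[1]]
      off <- off + exon_w[j]
    }
    genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
    names(genome) <- chrom
    gr <- GRanges(chrom, IRanges(block_start[tx_order], block_end[tx_order]),
                  strand = strand)
    genes <- GRangesList(geneF = gr)
    # genomic coordinate of spliced-CDS base 268: mRNA exon 3, offset 68
    b3 <- tx_order[3]
    if (strand == "+") {
      gpos <- block_start[b3] + 67L
      ref <- "A"; alt <- "G"
    } else {
      gpos <- block_end[b3] - 67L
      ref <- "T"; alt <- "C"   # plus-strand alleles of the A>G change
    }
    list(genome = genome, genes = genes,
         variant = data.frame(chrom = chrom, pos = gpos, ref = ref, alt = alt),
         cds_offset = 268L)
  })
}
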