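#' Read gene models (CDS) from a GFF3 file
#'
#' Imports the GFF3 with rtracklayer and assembles, for each gene, the
#' CDS segments of its first transcript in transcription order (left to
#' right on the plus strand, right to left on the minus strand). Genes
#' whose total CDS length is not a multiple of 3 are dropped with a
#' warning.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @return named GRangesList of CDS segments per gene, in transcription
#'   order.
#' @export
readGeneModels <- function(path) {
  g <- rtracklayer::import(path)
  type <- as.character(g$type)
  cds <- g[type == "CDS"]
  mrna <- g[type == "mRNA" | type == "transcript"]
  tx2gene <- stats::setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  cds_tx <- as.character(unlist(cds$Parent))
  cds_gene <- ifelse(cds_tx %in% names(tx2gene), tx2gene[cds_tx], cds_tx)
  # first transcript per gene only
  first_tx <- tapply(cds_tx, cds_gene, function(x) x[1])
  keep <- cds_tx == first_tx[cds_gene]
  cds <- cds[keep]; cds_gene <- cds_gene[keep]
  mcols(cds) <- NULL
  gl <- S4Vectors::split(cds, cds_gene)
  gl <- GRangesList(lapply(gl, function(x) {
    if (as.character(strand(x))[1] == "-") x[order(-start(x))]
    else x[order(start(x))]
  }))
  len3 <- sum(width(gl)) %% 3 == 0
  if (!all(len3)) {
    warning(sum(!len3), " gene(s) with CDS length not divisible by 3 dropped")
    gl <- gl[len3]
  }
  gl
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene) so that
#' \code{\link{readGeneModels}} round-trips.
#'
#' @param genes GRangesList of CDS per gene in transcription order.
#' @param path output file.
#' @export
writeGeneModelsGFF3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gid in names(genes)) {
    cds <- genes[[gid]]
    ch <- as.character(seqnames(cds))[1]
    st <- as.character(strand(cds))[1]
    lo <- min(start(cds)); hi <- max(end(cds))
    tid <- paste0(gid, ".1")
    lines <- c(lines,
      sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ch, lo, hi, st, gid),
      sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              ch, lo, hi, st, tid, gid),
      sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              ch, start(cds), end(cds), st, tid, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Genes overlapping a region
#'
#' Returns the gene ids whose span (first to last CDS base) overlaps the
#' region by at least one bp, sorted by gene start.
#'
#' @param region GRanges of length 1 (or chrom/start/end given separately
#'   through a length-3 list).
#' @param genes GRangesList of CDS per gene.
#' @return character vector of gene ids.
#' @export
genesInRegion <- function(region, genes) {
  spans <- unlist(range(genes))
  hits <- GenomicRanges::findOverlaps(spans, region, ignore.strand = TRUE)
  ids <- names(spans)[unique(S4Vectors::queryHits(hits))]
  ids[order(start(spans)[match(ids, names(spans))])]
}

#' Map a genomic position into spliced CDS coordinates
#'
#' Walks the gene's CDS segments in transcription order and returns the
#' 1-based offset of the position in the spliced CDS together with the
#' codon index ceil(cds_pos / 3); positions in introns, UTRs or outside
#' the gene return NULL (noncoding).
#'
#' @param chrom,pos genomic coordinate of the variant (anchor base).
#' @param gene GRanges of one gene's CDS in transcription order.
#' @return list(cds_pos, codon_index) or NULL.
#' @export
cdsPosition <- function(chrom, pos, gene) {
  on_chrom <- as.character(seqnames(gene)) == chrom
  if (!any(on_chrom)) return(NULL)
  minus <- as.character(strand(gene))[1] == "-"
  cum <- cumsum(c(0, width(gene)))
  for (i in seq_along(gene)) {
    if (!on_chrom[i]) next
    if (pos >= start(gene)[i] && pos <= end(gene)[i]) {
      off <- if (minus) end(gene)[i] - pos + 1L else pos - start(gene)[i] + 1L
      cds_pos <- cum[i] + off
      return(list(cds_pos = as.integer(cds_pos),
                  codon_index = as.integer(ceiling(cds_pos / 3))))
    }
  }
  NULL
}

# spliced CDS sequence of one gene (transcription orientation)
.splicedCDS <- function(gene, genome) {
  pieces <- lapply(seq_along(gene), function(i) {
    s <- Biostrings::subseq(genome[[as.character(seqnames(gene))[i]]],
                            start(gene)[i], end(gene)[i])
    if (as.character(strand(gene))[i] == "-")
      Biostrings::reverseComplement(s) else s
  })
  do.call(Biostrings::xscat, pieces)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding effect of a variant on a gene
#'
#' SNPs are translated through the standard genetic code: the reference
#' and alternate codons are compared (with reverse-complement handling on
#' minus-strand genes) and classified as synonymous, nonsynonymous,
#' stopgain or stoploss. Indels are frameshift when the length difference
#' between ref and alt is not a multiple of 3, non-frameshift otherwise.
#' Variants outside the spliced CDS are noncoding. The reference allele
#' must match the genome sequence at the position.
#'
#' @param chrom,pos,ref,alt the variant (VCF-style left-aligned alleles,
#'   plus-strand).
#' @param gene GRanges of one gene's CDS in transcription order.
#' @param genome DNAStringSet of the reference sequence.
#' @return list(effect, cds_pos, codon_index, ref_aa, alt_aa); effect is
#'   one of synonymous, nonsynonymous, stopgain, stoploss,
#'   frameshift_ins, frameshift_del, nonframeshift_ins,
#'   nonframeshift_del, noncoding.
#' @export
classifyEffect <- function(chrom, pos, ref, alt, gene, genome) {
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from the genome")
  gseq <- genome[[chrom]]
  have <- as.character(Biostrings::subseq(gseq, pos, pos + nchar(ref) - 1L))
  if (have != ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome has ", have, ", variant says ", ref, ")")
  cp <- cdsPosition(chrom, pos, gene)
  if (is.null(cp))
    return(list(effect = "noncoding", cds_pos = NA_integer_,
                codon_index = NA_integer_, ref_aa = NA, alt_aa = NA))
  if (nchar(ref) != nchar(alt)) {
    d <- nchar(alt) - nchar(ref)
    fs <- abs(d) %% 3 != 0
    eff <- paste0(if (fs) "frameshift_" else "nonframeshift_",
                  if (d > 0) "ins" else "del")
    return(list(effect = eff, cds_pos = cp$cds_pos,
                codon_index = cp$codon_index, ref_aa = NA, alt_aa = NA))
  }
  spliced <- .splicedCDS(gene, genome)
  ci <- cp$codon_index
  codon <- as.character(Biostrings::subseq(spliced, 3 * ci - 2, 3 * ci))
  minus <- as.character(strand(gene))[1] == "-"
  alt_tx <- if (minus) unname(.COMPLEMENT[alt]) else alt
  pos_in_codon <- cp$cds_pos - 3 * (ci - 1)
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_tx
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon]); alt_aa <- unname(code[alt_codon])
  eff <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stopgain"
  else if (ref_aa == "*") "stoploss"
  else "nonsynonymous"
  list(effect = eff, cds_pos = cp$cds_pos, codon_index = ci,
       ref_aa = ref_aa, alt_aa = alt_aa)
}

.AA_CHANGING <- c("nonsynonymous", "stopgain", "stoploss", "frameshift_ins",
                  "frameshift_del", "nonframeshift_ins", "nonframeshift_del")

#' Nominate candidate genes in fine-mapped regions
#'
#' A gene is a candidate when it lies in one of the regions and carries at
#' least one parent-differentiating variant whose coding effect changes
#' the protein (nonsynonymous, stop gain/loss, or any indel in the CDS).
#' Variants inside a region but not in any CDS are returned separately as
#' regulatory candidates, without effect claims.
#'
#' @param regions GRanges of candidate regions (e.g. from
#'   \code{\link{callCandidateRegions}}); names (or an mcols column
#'   \code{name}) label the output's QTL column.
#' @param variants data.frame(chrom, pos, ref, alt) of variants that
#'   differ between the parents.
#' @param genes GRangesList of CDS per gene.
#' @param genome DNAStringSet reference sequence.
#' @param descriptions optional named character vector (gene id ->
#'   functional description).
#' @return list with \code{candidates} (QTL, gene, position, ref, alt,
#'   effect, ref_aa, alt_aa, description) and \code{regulatory}
#'   (region-restricted noncoding variants with their nearest gene).
#' @export
candidateGenes <- function(regions, variants, genes, genome,
                           descriptions = NULL) {
  region_names <- if (!is.null(names(regions))) names(regions)
    else if ("name" %in% names(mcols(regions))) mcols(regions)$name
    else paste0("region", seq_along(regions))
  cand <- list(); reg <- list()
  spans <- unlist(range(genes))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    gids <- genesInRegion(r, genes)
    inreg <- variants$chrom == as.character(seqnames(r)) &
      variants$pos >= start(r) & variants$pos <= end(r)
    vr <- variants[inreg, , drop = FALSE]
    if (nrow(vr) == 0L) next
    coding_hit <- rep(FALSE, nrow(vr))
    for (gid in gids) {
      gene <- genes[[gid]]
      for (k in seq_len(nrow(vr))) {
        eff <- classifyEffect(vr$chrom[k], vr$pos[k], vr$ref[k], vr$alt[k],
                              gene, genome)
        if (eff$effect == "noncoding") next
        coding_hit[k] <- TRUE
        if (eff$effect %in% .AA_CHANGING)
          cand[[length(cand) + 1L]] <- data.frame(
            QTL = region_names[ri], gene = gid, position = vr$pos[k],
            ref = vr$ref[k], alt = vr$alt[k], effect = eff$effect,
            ref_aa = if (is.na(eff$ref_aa)) "" else eff$ref_aa,
            alt_aa = if (is.na(eff$alt_aa)) "" else eff$alt_aa,
            description = if (!is.null(descriptions) &&
                              gid %in% names(descriptions))
              descriptions[[gid]] else "")
      }
    }
    if (any(!coding_hit)) {
      vnc <- vr[!coding_hit, , drop = FALSE]
      near <- vapply(vnc$pos, function(p) {
        d <- abs((start(spans) + end(spans)) / 2 - p)
        d[as.character(seqnames(spans)) != as.character(seqnames(r))] <- Inf
        if (all(is.infinite(d))) NA_character_ else names(spans)[which.min(d)]
      }, "")
      reg[[length(reg) + 1L]] <- data.frame(
        QTL = region_names[ri], chrom = vnc$chrom, position = vnc$pos,
        ref = vnc$ref, alt = vnc$alt, nearest_gene = near)
    }
  }
  empty_c <- data.frame(QTL = character(), gene = character(),
                        position = numeric(), ref = character(),
                        alt = character(), effect = character(),
                        ref_aa = character(), alt_aa = character(),
                        description = character())
  list(candidates = if (length(cand)) do.call(rbind, cand) else empty_c,
       regulatory = if (length(reg)) do.call(rbind, reg) else
         data.frame(QTL = character(), chrom = character(),
                    position = numeric(), ref = character(),
                    alt = character(), nearest_gene = character()))
}
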