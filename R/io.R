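#' Write genotypes to a minimal VCF v4.2
#'
#' Emits a plain-text, GT-only VCF with the two parents as the first two
#' sample columns followed by the population. Parent calls come from the
#' site annotations; population calls are de-polarized back to ref/alt
#' genotypes.
#'
#' @param genotypes a \linkS4class{RilGenotypes}.
#' @param path output file.
#' @param parent_names names of the two parent columns.
#' @export
writeGenotypeVCF <- function(genotypes, path, parent_names = c("P1", "P2")) {
  gr <- rowRanges(genotypes)
  v <- genoCalls(genotypes)
  rd <- mcols(gr)
  lens <- seqlengths(gr)
  hdr <- c("##fileformat=VCFv4.2",
           if (!anyNA(lens))
             sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", parent_names, colnames(v)),
                 collapse = "\t"))
  gt_of_call <- c(HOM_REF = "0/0", HOM_ALT = "1/1", HET = "0/1",
                  MISSING = "./.")
  p1 <- gt_of_call[rd$p1_call]
  p2 <- gt_of_call[rd$p2_call]
  # de-polarize: code 0 (P1 genotype) becomes the p1 parental VCF genotype
  pop <- matrix("./.", nrow(v), ncol(v))
  pop[!is.na(v) & v == GT_HET] <- "0/1"
  isP1 <- !is.na(v) & v == GT_P1
  isP2 <- !is.na(v) & v == GT_P2
  pop[isP1] <- p1[row(v)[isP1]]
  pop[isP2] <- p2[row(v)[isP2]]
  body <- paste(as.character(seqnames(gr)), start(gr), ".", rd$ref, rd$alt,
                ".", "PASS", ".", "GT", p1, p2, sep = "\t")
  body <- paste(body, apply(pop, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GT-only VCF into polarized genotypes
#'
#' Parses a VCF v4.x with vcfR, keeps biallelic sites, polarizes the
#' population calls against the two named parent columns (sites where
#' either parent is heterozygous, missing, or where both share an allele
#' are annotated but can be removed with
#' \code{\link{filterParentInformative}}). Multi-allelic sites are skipped
#' with a count.
#'
#' @param path VCF file.
#' @param parent_names the two parent sample columns (default P1/P2).
#' @return list with \code{genotypes} (\linkS4class{RilGenotypes} of the
#'   non-parent samples) and \code{n_multiallelic} (skipped sites).
#' @export
readGenotypeVCF <- function(path, parent_names = c("P1", "P2")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!all(parent_names %in% colnames(gt)))
    stop("parent column(s) missing from VCF: ",
         paste(setdiff(parent_names, colnames(gt)), collapse = ", "))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  call_of <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("MISSING", length(g))
    out[g %in% "0/0"] <- "HOM_REF"
    out[g %in% "1/1"] <- "HOM_ALT"
    out[g %in% c("0/1", "1/0")] <- "HET"
    out
  }
  p1 <- call_of(gt[, parent_names[1]])
  p2 <- call_of(gt[, parent_names[2]])
  samples <- setdiff(colnames(gt), parent_names)
  pop <- gt[, samples, drop = FALSE]
  pop <- gsub("|", "/", pop, fixed = TRUE)
  pop[pop == "1/0"] <- "0/1"
  calls <- matrix(NA_integer_, nrow(pop), ncol(pop),
                  dimnames = list(NULL, samples))
  calls[which(pop == "0/1")] <- GT_HET
  hom0 <- !is.na(pop) & pop == "0/0"
  hom1 <- !is.na(pop) & pop == "1/1"
  p1_is_ref <- p1 == "HOM_REF"
  # polarization is meaningful only at parent-informative sites; elsewhere
  # hom calls fall back to ref-based coding (P1 = ref)
  calls[hom0] <- ifelse(p1_is_ref[row(pop)[hom0]], GT_P1, GT_P2)
  calls[hom1] <- ifelse(p1_is_ref[row(pop)[hom1]], GT_P2, GT_P1)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  gr <- GRanges(fix[, "CHROM"],
                IRanges(as.integer(fix[, "POS"]), width = nchar(ref)))
  mcols(gr) <- DataFrame(
    ref = ref, alt = alt,
    vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "indel"),
    p1_call = p1, p2_call = p2)
  list(genotypes = RilGenotypes(gr, calls, samples),
       n_multiallelic = sum(multi))
}

#' Write / read the phenotype table
#'
#' Plain TSV with columns sample, trait, environment, value.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a bin map as TSV
#'
#' Columns chrom, start, end then one genotype column per sample coded
#' 0 = P1, 1 = heterozygous, 2 = P2, NA = missing.
#'
#' @param binmap a \linkS4class{BinMap}.
#' @param path file path.
#' @export
writeBinMap <- function(binmap, path) {
  gr <- rowRanges(binmap)
  df <- cbind(data.frame(bin = names(gr),
                         chrom = as.character(seqnames(gr)),
                         start = start(gr), end = end(gr)),
              as.data.frame(genoCalls(binmap)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinMap
#' @param chrom_lengths optional named chromosome lengths for the seqinfo.
#' @export
readBinMap <- function(path, chrom_lengths = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("bin", "chrom", "start", "end")
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(geno) <- "integer"
  si <- if (is.null(chrom_lengths)) NULL else
    Seqinfo(names(chrom_lengths), unlist(chrom_lengths))
  gr <- if (is.null(si)) GRanges(df$chrom, IRanges(df$start, df$end)) else
    GRanges(df$chrom, IRanges(df$start, df$end), seqinfo = si)
  names(gr) <- df$bin
  se <- SummarizedExperiment(assays = list(geno = geno), rowRanges = gr)
  new("BinMap", se)
}

#' Write a genetic map as TSV
#'
#' @param linkage_map a \linkS4class{LinkageMap}.
#' @param path file path.
#' @export
writeLinkageMap <- function(linkage_map, path) {
  utils::write.table(mapTable(linkage_map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive regions to BED (0-based half-open) and back
#'
#' @param gr GRanges (1-based inclusive, the package-wide convention).
#' @param path BED file path.
#' @export
writeRegionsBED <- function(gr, path) {
  nm <- if (!is.null(names(gr))) names(gr) else
    paste0("region", seq_along(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), name = nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionsBED
#' @export
readRegionsBED <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  gr <- GRanges(df$V1, IRanges(df$V2 + 1L, df$V3))
  if (ncol(df) >= 4) names(gr) <- df$V4
  gr
}
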