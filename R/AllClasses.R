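#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlengths<- Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Simulation configuration for a RIL mapping study
#'
#' Holds every parameter of the synthetic recombinant-inbred-line (RIL)
#' study: the genome layout (chromosome lengths in bp and Morgans), the
#' variant catalog size, the population design (number of lines and selfing
#' generations), the genotyping noise model, and the causal loci that drive
#' the binary traits.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{length_bp},
#'   \code{length_morgans}.
#' @slot n_variants integer vector, one catalog size per chromosome.
#' @slot n_rils number of RILs to simulate.
#' @slot selfing_generations number of selfing rounds after the F1; the
#'   population is the F(g+1) generation and expected residual
#'   heterozygosity is (1/2)^g.
#' @slot missing_rate probability an observed genotype call is dropped.
#' @slot error_rate probability a homozygous call flips to the other parent.
#' @slot het_call_rate probability a homozygous call is miscalled heterozygous.
#' @slot indel_fraction fraction of catalog sites simulated as indels.
#' @slot causal_loci data.frame with columns \code{chrom}, \code{pos},
#'   \code{trait}, \code{penetrance}.
#' @slot environments labels of the phenotyping environments.
#' @slot seed integer RNG seed; every generator derives its stream from it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  chromosomes = "data.frame",
  n_variants = "integer",
  n_rils = "integer",
  selfing_generations = "integer",
  missing_rate = "numeric",
  error_rate = "numeric",
  het_call_rate = "numeric",
  indel_fraction = "numeric",
  causal_loci = "data.frame",
  environments = "character",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  ch <- object@chromosomes
  if (!all(c("name", "length_bp", "length_morgans") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns name, length_bp, length_morgans")
  else {
    if (any(ch$length_bp <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
    if (any(ch$length_morgans < 0)) msg <- c(msg, "genetic lengths must be >= 0")
    if (anyDuplicated(ch$name)) msg <- c(msg, "duplicate chromosome names")
  }
  if (length(object@n_variants) != nrow(ch))
    msg <- c(msg, "n_variants must have one entry per chromosome")
  if (any(object@n_variants < 1)) msg <- c(msg, "need at least one variant per chromosome")
  rates <- c(object@missing_rate, object@error_rate, object@het_call_rate,
             object@indel_fraction)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "all rates must lie in [0, 1]")
  if (object@n_rils < 1) msg <- c(msg, "n_rils must be >= 1")
  if (object@selfing_generations < 1) msg <- c(msg, "selfing_generations must be >= 1")
  cl <- object@causal_loci
  if (nrow(cl)) {
    if (!all(c("chrom", "pos", "trait", "penetrance") %in% names(cl)))
      msg <- c(msg, "causal_loci needs columns chrom, pos, trait, penetrance")
    else {
      bad <- !(cl$chrom %in% ch$name)
      if (any(bad)) msg <- c(msg, "causal locus on unknown chromosome")
      else {
        lim <- ch$length_bp[match(cl$chrom, ch$name)]
        if (any(cl$pos < 1 | cl$pos > lim))
          msg <- c(msg, "causal position outside chromosome bounds")
      }
      if (any(cl$penetrance <= 0.5 | cl$penetrance > 1))
        msg <- c(msg, "penetrance must lie in (0.5, 1]")
      if (anyDuplicated(cl$trait)) msg <- c(msg, "duplicate trait names")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults emulate the mapping study the package models: a nine-chromosome
#' ~401-Mb genome carrying 46,023 markers distributed very unevenly among
#' chromosomes, 400 RILs at the F7 generation (six selfing rounds after the
#' F1), low-coverage genotyping noise, and two unlinked monogenic binary
#' traits (anther colour on Chr6 at ~34.15 Mb, hull colour on Chr1 at
#' ~5.5 Mb) with near-complete penetrance.
#'
#' @param chromosomes data.frame(name, length_bp, length_morgans).
#' @param n_variants per-chromosome catalog sizes (recycled if scalar).
#' @param n_rils population size.
#' @param selfing_generations selfing rounds after the F1 (default 6 = F7).
#' @param missing_rate,error_rate,het_call_rate genotyping noise model.
#' @param indel_fraction fraction of sites simulated as indels.
#' @param causal_loci data.frame(chrom, pos, trait, penetrance).
#' @param environments phenotyping environment labels.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(chromosomes = data.frame(name = "Chr1", length_bp = 1e6,
#'                                           length_morgans = 0.5),
#'                  n_variants = 200, n_rils = 50, causal_loci = NULL)
#' @export
simConfig <- function(chromosomes = NULL,
                      n_variants = NULL,
                      n_rils = 400L,
                      selfing_generations = 6L,
                      missing_rate = 0.3,
                      error_rate = 0.01,
                      het_call_rate = 0.02,
                      indel_fraction = 0.066,
                      causal_loci = NULL,
                      environments = c("18CD", "18AY", "19CD", "19AY"),
                      seed = 1L) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(
      name = paste0("Chr", 1:9),
      length_bp = c(42145699, 49200776, 50652576, 40408058, 47253416,
                    36015257, 35964515, 40690061, 58970518),
      length_morgans = rep(1.5, 9))
    if (is.null(n_variants))
      n_variants <- c(467L, 1402L, 7983L, 403L, 3687L, 2983L, 1225L,
                      15315L, 12558L)
    if (is.null(causal_loci))
      causal_loci <- data.frame(
        chrom = c("Chr6", "Chr1"), pos = c(34150000, 5500000),
        trait = c("AC", "HC"), penetrance = c(0.97, 0.97))
  }
  if (is.null(n_variants))
    stop("n_variants must be given with custom chromosomes")
  if (is.null(causal_loci))
    causal_loci <- data.frame(chrom = character(), pos = numeric(),
                              trait = character(), penetrance = numeric())
  n_variants <- rep_len(as.integer(n_variants), nrow(chromosomes))
  new("SimConfig",
      chromosomes = chromosomes, n_variants = n_variants,
      n_rils = as.integer(n_rils),
      selfing_generations = as.integer(selfing_generations),
      missing_rate = missing_rate, error_rate = error_rate,
      het_call_rate = het_call_rate, indel_fraction = indel_fraction,
      causal_loci = causal_loci, environments = environments,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", nrow(object@chromosomes), "chromosomes,",
      sum(object@n_variants), "variants,", object@n_rils, "RILs (F",
      object@selfing_generations + 1L, ")\n", sep = " ")
  cat("  noise: missing", object@missing_rate, "error", object@error_rate,
      "het-call", object@het_call_rate, "\n")
  if (nrow(object@causal_loci))
    cat("  traits:", paste(object@causal_loci$trait, collapse = ", "), "\n")
})

#' Parent-polarized RIL genotype calls
#'
#' A \code{RangedSummarizedExperiment} whose rows are variant sites (with
#' ref/alt alleles, variant type and the two parental calls in
#' \code{rowData}) and whose single assay \code{"calls"} holds the
#' parent-polarized population genotypes coded 0 = P1 homozygote,
#' 1 = heterozygote, 2 = P2 homozygote, NA = missing.
#'
#' @exportClass RilGenotypes
setClass("RilGenotypes", contains = "RangedSummarizedExperiment")

setValidity("RilGenotypes", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    v <- SummarizedExperiment::assay(object, "calls")
    if (!all(v %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype codes must be 0/1/2/NA")
  }
  rd <- mcols(rowRanges(object))
  need <- c("ref", "alt", "vtype", "p1_call", "p2_call")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData needs columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a RilGenotypes object
#'
#' @param sites GRanges with mcols \code{ref}, \code{alt}, \code{vtype},
#'   \code{p1_call}, \code{p2_call}.
#' @param calls integer site-by-sample matrix coded 0/1/2/NA.
#' @param sampleNames optional sample names (else taken from the matrix).
#' @return A \linkS4class{RilGenotypes}.
#' @export
RilGenotypes <- function(sites, calls, sampleNames = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sampleNames))
    sampleNames <- sprintf("RIL%03d", seq_len(ncol(calls)))
  colnames(calls) <- sampleNames
  se <- SummarizedExperiment(assays = list(calls = calls), rowRanges = sites)
  new("RilGenotypes", se)
}

setMethod("show", "RilGenotypes", function(object) {
  v <- SummarizedExperiment::assay(object, "calls")
  cat("RilGenotypes:", nrow(object), "sites x", ncol(object), "samples\n")
  cat(sprintf("  missing %.1f%%, het %.1f%% of calls\n",
              100 * mean(is.na(v)), 100 * mean(v == 1L, na.rm = TRUE)))
})

#' Population bin map
#'
#' A \code{RangedSummarizedExperiment} whose rows are recombination bins —
#' maximal genome segments within which no sampled RIL carries a breakpoint
#' — and whose assay \code{"geno"} holds each sample's bin genotype
#' (0/1/2/NA coding as in \linkS4class{RilGenotypes}).
#'
#' @exportClass BinMap
setClass("BinMap", contains = "RangedSummarizedExperiment")

setValidity("BinMap", function(object) {
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  TRUE
})

setMethod("show", "BinMap", function(object) {
  cat("BinMap:", nrow(object), "bins x", ncol(object), "samples on",
      length(unique(as.character(seqnames(rowRanges(object))))),
      "chromosome(s)\n")
  w <- width(rowRanges(object))
  cat(sprintf("  bin width %.1f kb median (%.1f kb - %.1f kb)\n",
              stats::median(w) / 1e3, min(w) / 1e3, max(w) / 1e3))
})

#' Genetic (linkage) map over bin markers
#'
#' Ordered bins per chromosome with observed recombinant fractions between
#' adjacent bins, single-meiosis fractions after RIL correction, Kosambi
#' interval distances and cumulative cM positions.
#'
#' @slot map data.frame with columns \code{bin}, \code{chrom}, \code{start},
#'   \code{end}, \code{r_obs}, \code{r}, \code{interval_cM}, \code{cum_cM},
#'   \code{n_informative}.
#' @exportClass LinkageMap
setClass("LinkageMap", representation(map = "data.frame"))

setValidity("LinkageMap", function(object) {
  m <- object@map
  need <- c("bin", "chrom", "start", "end", "interval_cM", "cum_cM")
  if (!all(need %in% names(m)))
    return(paste("map needs columns:", paste(need, collapse = ", ")))
  if (any(m$interval_cM < 0, na.rm = TRUE)) return("interval_cM must be >= 0")
  ok <- all(unlist(lapply(split(m$cum_cM, m$chrom), function(x) !is.unsorted(x))))
  if (!ok) return("cumulative cM must be non-decreasing within chromosome")
  TRUE
})

#' @describeIn LinkageMap-class the underlying map table.
#' @param x a LinkageMap.
#' @export
mapTable <- function(x) x@map

#' @describeIn LinkageMap-class total map length in cM (sum over chromosomes).
#' @export
totalMapLength <- function(x) {
  sum(vapply(split(x@map$cum_cM, x@map$chrom), max, numeric(1)))
}

#' @describeIn LinkageMap-class mean adjacent-bin interval in cM,
#'   total cM / (bins - chromosomes).
#' @export
meanBinInterval <- function(x) {
  totalMapLength(x) / (nrow(x@map) - length(unique(x@map$chrom)))
}

setMethod("show", "LinkageMap", function(object) {
  cat("LinkageMap:", nrow(object@map), "bins on",
      length(unique(object@map$chrom)), "chromosome(s),",
      sprintf("%.1f cM total, %.2f cM mean interval\n",
              totalMapLength(object), meanBinInterval(object)))
})

#' Extract genotype call matrix
#'
#' @param x a \linkS4class{RilGenotypes} or \linkS4class{BinMap}.
#' @return integer matrix coded 0/1/2/NA.
#' @export
genoCalls <- function(x) {
  if (is(x, "BinMap")) SummarizedExperiment::assay(x, "geno")
  else SummarizedExperiment::assay(x, "calls")
}

#' Extract site or bin coordinates
#'
#' @param x a \linkS4class{RilGenotypes} or \linkS4class{BinMap}.
#' @return the GRanges of variant sites or bins.
#' @export
siteRanges <- function(x) rowRanges(x)
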