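#' Keep only parent-informative variant sites
#'
#' A site is informative for a biparental RIL design only when both parents
#' are homozygous, neither call is missing, and the two calls differ.
#' Sites where either parent is heterozygous or missing, or where the
#' parents share the same allele, are removed.
#'
#' @param sites GRanges with mcols \code{p1_call} and \code{p2_call}
#'   (values HOM_REF/HOM_ALT/HET/MISSING).
#' @return list with \code{sites} (retained GRanges) and \code{report}
#'   (counts per removal rule).
#' @export
filterParentInformative <- function(sites) {
  p1 <- mcols(sites)$p1_call
  p2 <- mcols(sites)$p2_call
  hom <- c("HOM_REF", "HOM_ALT")
  bad_het  <- p1 == "HET" | p2 == "HET"
  bad_miss <- p1 == "MISSING" | p2 == "MISSING"
  both_hom <- p1 %in% hom & p2 %in% hom
  bad_same <- both_hom & p1 == p2
  keep <- both_hom & p1 != p2
  report <- list(
    n_input = length(sites), n_retained = sum(keep),
    removed = c(parent_het = sum(bad_het), parent_missing = sum(bad_miss),
                no_difference = sum(bad_same)),
    n_removed = sum(!keep))
  list(sites = sites[keep], keep = keep, report = report)
}

#' Population-scale site filtering
#'
#' Applies the population quality rules to a parent-polarized genotype
#' matrix. A site is retained iff its minor allele frequency (computed over
#' homozygous, non-missing calls as min of the two parental-allele
#' frequencies) is at least \code{maf_min}, its missing fraction (over all
#' samples) is at most \code{miss_max}, and its heterozygous fraction
#' (over non-missing calls) is at most \code{het_max}. Thresholds are
#' inclusive for retention: a site exactly at a boundary is kept.
#'
#' @param genotypes a \linkS4class{RilGenotypes}.
#' @param maf_min minimum minor allele frequency (default 0.1).
#' @param miss_max maximum missing fraction (default 0.5).
#' @param het_max maximum heterozygous fraction (default 0.2).
#' @return list with \code{genotypes} (filtered) and \code{report}.
#' @export
filterPopulation <- function(genotypes, maf_min = 0.1, miss_max = 0.5,
                             het_max = 0.2) {
  v <- genoCalls(genotypes)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty genotype matrix")
  ns <- ncol(v)
  n0 <- rowSums(v == GT_P1, na.rm = TRUE)
  n2 <- rowSums(v == GT_P2, na.rm = TRUE)
  n1 <- rowSums(v == GT_HET, na.rm = TRUE)
  nmiss <- rowSums(is.na(v))
  nonmiss <- ns - nmiss
  maf <- ifelse(n0 + n2 > 0, pmin(n0, n2) / (n0 + n2), 0)
  missf <- nmiss / ns
  hetf <- ifelse(nonmiss > 0, n1 / nonmiss, 1)
  fail_maf <- maf < maf_min
  fail_miss <- missf > miss_max
  fail_het <- hetf > het_max
  keep <- !(fail_maf | fail_miss | fail_het)
  report <- list(
    n_input = nrow(v), n_retained = sum(keep), n_removed = sum(!keep),
    removed = c(maf = sum(fail_maf), missing = sum(fail_miss),
                het = sum(fail_het)))
  list(genotypes = genotypes[keep, ], report = report,
       stats = data.frame(maf = maf, missing = missf, het = hetf))
}

#' Screen samples by heterozygosity
#'
#' Per-sample heterozygosity is the fraction of heterozygous calls among
#' non-missing calls; samples above \code{cutoff} (or with no data at all)
#' are removed. At an advanced selfing generation residual heterozygosity
#' is expected near (1/2)^g, so a high value flags contaminated or
#' mislabelled lines.
#'
#' @param genotypes a \linkS4class{RilGenotypes}.
#' @param cutoff maximum tolerated heterozygosity (default 0.3).
#' @return list with \code{genotypes} (retained samples), \code{het}
#'   (named per-sample heterozygosity) and \code{report}.
#' @export
sampleHeterozygosity <- function(genotypes, cutoff = 0.3) {
  v <- genoCalls(genotypes)
  nonmiss <- colSums(!is.na(v))
  nhet <- colSums(v == GT_HET, na.rm = TRUE)
  het <- ifelse(nonmiss > 0, nhet / nonmiss, NA_real_)
  names(het) <- colnames(v)
  no_data <- nonmiss == 0
  keep <- !no_data & het <= cutoff
  report <- list(
    n_input = ncol(v), n_retained = sum(keep), n_removed = sum(!keep),
    removed_samples = data.frame(
      sample = colnames(v)[!keep], het = het[!keep],
      reason = ifelse(no_data[!keep], "no data", "heterozygosity")))
  list(genotypes = genotypes[, keep], het = het, report = report)
}

#' Variant density per window
#'
#' Density of variants per fixed-size window (50 kb by default), i.e.
#' count * window / chromosome length, rounded to 2 decimals — the
#' convention used in per-chromosome marker summaries.
#'
#' @param counts per-chromosome variant counts.
#' @param lengths per-chromosome lengths in bp.
#' @param window window size in bp (default 50000).
#' @return numeric vector of densities.
#' @examples
#' variantDensity(15315, 40690061)   # 18.82
#' @export
variantDensity <- function(counts, lengths, window = 50000) {
  stopifnot(all(lengths > 0))
  round(counts * window / lengths, 2)
}
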