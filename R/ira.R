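#' Split RILs into phenotype groups
#'
#' Group A holds the samples showing the P1-parent phenotype (trait value
#' 0), group B those showing the P2-parent phenotype (value 1). When the
#' phenotype was scored in several environments the per-sample consensus
#' (majority vote across environments) is used; samples with a missing or
#' tied consensus are excluded.
#'
#' @param pheno phenotype data.frame (sample, trait, environment, value).
#' @param trait trait name to split on.
#' @return list(A = character vector of samples, B = character vector).
#' @export
splitGroups <- function(pheno, trait) {
  ph <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(ph) == 0L) stop("no phenotype records for trait ", trait)
  mv <- tapply(ph$value, ph$sample, mean)
  a <- names(mv)[mv < 0.5]
  b <- names(mv)[mv > 0.5]
  if (length(a) == 0L) stop("empty group A (no P1-phenotype samples)")
  if (length(b) == 0L) stop("empty group B (no P2-phenotype samples)")
  list(A = a, B = b)
}

#' Mark loci eligible for inconsistent rate analysis
#'
#' A locus can be used only when the parents are homozygous for different
#' alleles (guaranteed after polarization) and both its missing fraction
#' and heterozygous fraction in the population are at most 50 percent.
#'
#' @param genotypes a \linkS4class{RilGenotypes}.
#' @param miss_max,het_max eligibility bounds (default 0.5 each).
#' @return logical vector over sites.
#' @export
iraEligible <- function(genotypes, miss_max = 0.5, het_max = 0.5) {
  v <- genoCalls(genotypes)
  ns <- ncol(v)
  nmiss <- rowSums(is.na(v))
  nhet <- rowSums(v == GT_HET, na.rm = TRUE)
  nonmiss <- ns - nmiss
  (nmiss / ns) <= miss_max &
    ifelse(nonmiss > 0, nhet / nonmiss, 1) <= het_max
}

#' Per-locus inconsistent rates for both phenotype groups
#'
#' Within the RILs of phenotype group A, the inconsistent rate of a locus
#' is the number of samples with the B-parent genotype divided by the
#' number with either homozygous parental genotype (heterozygous and
#' missing calls enter neither numerator nor denominator); symmetrically
#' for group B. Near a causal locus the wrong-parent genotype is rare, so
#' the rate approaches 0; at unlinked loci it approaches 0.5.
#'
#' @param genotypes a \linkS4class{RilGenotypes}.
#' @param groups list(A=, B=) from \code{\link{splitGroups}}.
#' @param eligible optional logical vector from \code{\link{iraEligible}}
#'   (computed if missing); ineligible loci get NA rates.
#' @return data.frame per locus: chrom, pos, rate_A, rate_B, n_A, n_B.
#' @export
locusInconsistentRates <- function(genotypes, groups, eligible = NULL) {
  v <- genoCalls(genotypes)
  if (is.null(eligible)) eligible <- iraEligible(genotypes)
  gA <- intersect(groups$A, colnames(v))
  gB <- intersect(groups$B, colnames(v))
  if (length(gA) == 0L || length(gB) == 0L)
    stop("phenotype groups do not overlap the genotyped samples")
  vA <- v[, gA, drop = FALSE]; vB <- v[, gB, drop = FALSE]
  aP1 <- rowSums(vA == GT_P1, na.rm = TRUE)
  aP2 <- rowSums(vA == GT_P2, na.rm = TRUE)
  bP1 <- rowSums(vB == GT_P1, na.rm = TRUE)
  bP2 <- rowSums(vB == GT_P2, na.rm = TRUE)
  rate_A <- ifelse(aP1 + aP2 > 0, aP2 / (aP1 + aP2), NA_real_)
  rate_B <- ifelse(bP1 + bP2 > 0, bP1 / (bP1 + bP2), NA_real_)
  rate_A[!eligible] <- NA_real_
  rate_B[!eligible] <- NA_real_
  gr <- rowRanges(genotypes)
  data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
             rate_A = rate_A, rate_B = rate_B,
             n_A = aP1 + aP2, n_B = bP1 + bP2)
}

#' Sliding-window average of inconsistent rates
#'
#' Averages the per-locus rates of each group in fixed physical windows
#' (50 kb wide, 10 kb step by default) anchored at coordinate 1 of every
#' chromosome; a window's mean is the arithmetic mean of the non-NA locus
#' rates at positions inside it, NA when it holds none.
#'
#' @param rates per-locus table from \code{\link{locusInconsistentRates}}.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window window width in bp (default 50000).
#' @param step window step in bp (default 10000).
#' @return data.frame per window: chrom, start, end, mean_rate_A,
#'   mean_rate_B, n_loci.
#' @export
iraWindowScan <- function(rates, chrom_lengths, window = 50000,
                          step = 10000) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1, max(L - 1, 1), by = step)
    starts <- starts[starts <= L]
    ends <- pmin(starts + window - 1, L)
    rc <- rates[rates$chrom == ch, , drop = FALSE]
    rc <- rc[order(rc$pos), , drop = FALSE]
    okA <- !is.na(rc$rate_A); okB <- !is.na(rc$rate_B)
    ok <- okA | okB
    pos <- rc$pos[ok]
    rA <- rc$rate_A[ok]; rB <- rc$rate_B[ok]
    csA <- c(0, cumsum(ifelse(is.na(rA), 0, rA)))
    cnA <- c(0, cumsum(!is.na(rA)))
    csB <- c(0, cumsum(ifelse(is.na(rB), 0, rB)))
    cnB <- c(0, cumsum(!is.na(rB)))
    lo <- findInterval(starts - 1, pos)      # loci strictly before window
    hi <- findInterval(ends, pos)            # loci at or before window end
    nA <- cnA[hi + 1] - cnA[lo + 1]
    nB <- cnB[hi + 1] - cnB[lo + 1]
    mA <- ifelse(nA > 0, (csA[hi + 1] - csA[lo + 1]) / nA, NA_real_)
    mB <- ifelse(nB > 0, (csB[hi + 1] - csB[lo + 1]) / nB, NA_real_)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            mean_rate_A = mA, mean_rate_B = mB,
                            n_loci = hi - lo)
  }
  do.call(rbind, out)
}

#' Call candidate regions from window-averaged inconsistent rates
#'
#' Windows where BOTH groups' mean rates are strictly below \code{cutoff}
#' (and at least \code{min_loci} informative loci are present) are marked;
#' overlapping or adjacent marked windows are merged into maximal
#' candidate regions, as are regions separated by less than one window
#' width (\code{merge_gap}): a gap narrower than the averaging window is
#' below the scan's resolution and cannot support two distinct candidate
#' intervals. Region bounds are the union of the marked window spans (so
#' they stay aligned to the window grid); the first and last eligible
#' locus inside each region are also reported as tight bounds.
#'
#' @param windows window table from \code{\link{iraWindowScan}}.
#' @param rates per-locus table (for the tight bounds).
#' @param cutoff rate cutoff (default 0.10, strict).
#' @param min_loci minimum informative loci per window (default 3).
#' @param merge_gap merge regions separated by fewer than this many bp
#'   (default 50000, the window width).
#' @return GRanges of candidate regions with mcols n_windows, min_rate_A,
#'   min_rate_B, mean_rate_A, mean_rate_B, tight_start, tight_end.
#' @export
callCandidateRegions <- function(windows, rates = NULL, cutoff = 0.10,
                                 min_loci = 3L, merge_gap = 50000L) {
  marked <- !is.na(windows$mean_rate_A) & !is.na(windows$mean_rate_B) &
    windows$mean_rate_A < cutoff & windows$mean_rate_B < cutoff &
    windows$n_loci >= min_loci
  if (!any(marked)) return(GRanges())
  w <- windows[marked, , drop = FALSE]
  gr <- GRanges(w$chrom, IRanges(w$start, w$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max(1L, merge_gap))
  ov <- GenomicRanges::findOverlaps(gr, red)
  idx <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  mcols(red)$n_windows <- lengths(idx)
  mcols(red)$min_rate_A <- vapply(idx, function(i) min(w$mean_rate_A[i]), 1)
  mcols(red)$min_rate_B <- vapply(idx, function(i) min(w$mean_rate_B[i]), 1)
  mcols(red)$mean_rate_A <- vapply(idx, function(i) mean(w$mean_rate_A[i]), 1)
  mcols(red)$mean_rate_B <- vapply(idx, function(i) mean(w$mean_rate_B[i]), 1)
  if (!is.null(rates)) {
    el <- rates[!is.na(rates$rate_A) | !is.na(rates$rate_B), , drop = FALSE]
    ts <- te <- rep(NA_real_, length(red))
    for (i in seq_along(red)) {
      inr <- el$chrom == as.character(seqnames(red))[i] &
        el$pos >= start(red)[i] & el$pos <= end(red)[i]
      if (any(inr)) { ts[i] <- min(el$pos[inr]); te[i] <- max(el$pos[inr]) }
    }
    mcols(red)$tight_start <- ts
    mcols(red)$tight_end <- te
  }
  red
}

#' Inconsistent rate analysis, end to end
#'
#' Convenience wrapper: split the population on a trait, compute per-locus
#' inconsistent rates on eligible loci, window-average them, and call the
#' candidate regions.
#'
#' @param genotypes a \linkS4class{RilGenotypes} (full eligible marker set,
#'   not only bin-map markers).
#' @param pheno phenotype table.
#' @param trait trait to analyse.
#' @param window,step,cutoff,min_loci see the component functions.
#' @return list(groups, rates, windows, regions).
#' @export
iraScan <- function(genotypes, pheno, trait, window = 50000, step = 10000,
                    cutoff = 0.10, min_loci = 3L) {
  groups <- splitGroups(pheno, trait)
  rates <- locusInconsistentRates(genotypes, groups)
  gr <- rowRanges(genotypes)
  lens <- seqlengths(gr)
  if (anyNA(lens))
    lens[is.na(lens)] <- vapply(seqlevels(gr)[is.na(lens)], function(ch)
      max(end(gr[seqnames(gr) == ch])), numeric(1))
  windows <- iraWindowScan(rates, as.list(lens), window, step)
  regions <- callCandidateRegions(windows, rates, cutoff, min_loci)
  list(groups = groups, rates = rates, windows = windows, regions = regions)
}
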