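#' Observed recombinant fraction between two bin genotype columns
#'
#' Counts samples whose homozygous genotypes disagree between the two
#' bins, over samples homozygous and non-missing at both; heterozygous or
#' missing calls at either bin are excluded.
#'
#' @param geno_a,geno_b integer genotype vectors (0/1/2/NA) over the same
#'   samples.
#' @return list with \code{R_obs} and \code{n_informative}.
#' @export
recombinationFraction <- function(geno_a, geno_b) {
  hom <- !is.na(geno_a) & !is.na(geno_b) &
    geno_a != GT_HET & geno_b != GT_HET
  n <- sum(hom)
  if (n == 0L) return(list(R_obs = NA_real_, n_informative = 0L))
  list(R_obs = sum(geno_a[hom] != geno_b[hom]) / n, n_informative = n)
}

#' RIL-by-selfing recombination correction
#'
#' For recombinant inbred lines produced by repeated selfing, the observed
#' recombinant fraction R between two loci is inflated relative to the
#' single-meiosis fraction r: R = 2r/(1 + 2r) at fixation. Inverting gives
#' r = R / (2(1 - R)), capped below 0.5.
#'
#' @param R_obs observed recombinant fraction in [0, 1).
#' @param cap upper cap on r (default 0.4999).
#' @return single-meiosis recombination fraction r.
#' @export
rilCorrect <- function(R_obs, cap = 0.4999) {
  if (any(R_obs >= 1 | R_obs < 0, na.rm = TRUE))
    stop("R_obs must lie in [0, 1)")
  pmin(R_obs / (2 * (1 - R_obs)), cap)
}

#' Kosambi mapping function
#'
#' cM = 25 ln((1 + 2r)/(1 - 2r)). Monotone increasing, approximately 100 r
#' for small r, with implicit crossover interference.
#'
#' @param r single-meiosis recombination fraction in [0, 0.5).
#' @return genetic distance in cM.
#' @export
kosambiCM <- function(r) {
  if (any(r >= 0.5 | r < 0, na.rm = TRUE))
    stop("r must lie in [0, 0.5); apply rilCorrect() upstream")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param cm genetic distance in cM.
#' @return recombination fraction r, the exact inverse of
#'   \code{\link{kosambiCM}}.
#' @export
kosambiInverse <- function(cm) {
  e <- exp(cm / 25)
  (e - 1) / (2 * (e + 1))
}

#' Build a genetic map from a bin map
#'
#' Bins are kept in physical order per chromosome. Each adjacent-pair
#' interval distance is the observed recombinant fraction converted to a
#' single-meiosis fraction (\code{\link{rilCorrect}}, unless disabled)
#' and then to cM via \code{\link{kosambiCM}}; cumulative positions start
#' at 0 per chromosome. Intervals with zero informative samples get
#' distance 0 with a warning.
#'
#' @param binmap a \linkS4class{BinMap}.
#' @param use_ril_correction apply the RIL correction (default TRUE).
#' @return a \linkS4class{LinkageMap}.
#' @export
buildLinkageMap <- function(binmap, use_ril_correction = TRUE) {
  geno <- genoCalls(binmap)
  gr <- rowRanges(binmap)
  if (is.null(names(gr)))
    names(gr) <- sprintf("%s_bin%d", as.character(seqnames(gr)),
                         stats::ave(rep(1L, length(gr)),
                                    as.character(seqnames(gr)),
                                    FUN = seq_along))
  chroms <- unique(as.character(seqnames(gr)))
  rows <- list()
  for (ch in chroms) {
    idx <- which(as.character(seqnames(gr)) == ch)
    idx <- idx[order(start(gr[idx]))]
    k <- length(idx)
    r_obs <- rep(NA_real_, k); ninf <- rep(0L, k); dcm <- rep(0, k)
    if (k >= 2L) {
      for (j in 2:k) {
        rf <- recombinationFraction(geno[idx[j - 1L], ], geno[idx[j], ])
        ninf[j] <- rf$n_informative
        if (rf$n_informative == 0L) {
          warning("no informative samples between bins ", j - 1L, " and ",
                  j, " on ", ch, "; interval set to 0 cM")
          r_obs[j] <- NA_real_; dcm[j] <- 0
        } else {
          r_obs[j] <- rf$R_obs
          r <- if (use_ril_correction) rilCorrect(rf$R_obs)
               else min(rf$R_obs, 0.4999)
          dcm[j] <- kosambiCM(r)
        }
      }
    }
    rows[[ch]] <- data.frame(
      bin = names(gr)[idx], chrom = ch,
      start = start(gr[idx]), end = end(gr[idx]),
      r_obs = r_obs, n_informative = ninf,
      interval_cM = dcm, cum_cM = cumsum(dcm))
  }
  new("LinkageMap", map = do.call(rbind, rows))
}
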