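#' Pearson correlations between trait-environment phenotype columns
#'
#' Spreads the long phenotype table into one column per trait-environment
#' combination and returns the pairwise Pearson correlation matrix
#' (pairwise-complete observations; zero-variance columns give NA).
#'
#' @param pheno data.frame with columns \code{sample}, \code{trait},
#'   \code{environment}, \code{value}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
traitCorrelations <- function(pheno) {
  key <- paste0(pheno$trait, pheno$environment)
  cols <- unique(key)
  if (length(cols) < 2L) stop("need at least 2 trait-environment columns")
  samples <- unique(pheno$sample)
  m <- matrix(NA_real_, length(samples), length(cols),
              dimnames = list(samples, cols))
  m[cbind(match(pheno$sample, samples), match(key, cols))] <- pheno$value
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

# additive coding for the regression scan: P1 -> +1, HET -> 0, P2 -> -1
.markerCode <- function(geno) 1 - as.numeric(geno)

# Vectorised single-marker regression LOD over a marker matrix X (samples
# x markers, additive codes with NA) and phenotype matrix Y (samples x K,
# no NA). Missing marker calls are dropped pairwise via mask algebra.
.scanLODMatrix <- function(X, Y, lod_max = 50, min_n = 10L) {
  Y <- as.matrix(Y)
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0
  nj <- colSums(M)
  SY <- crossprod(M, Y)                 # p x K
  SYY <- crossprod(M, Y^2)
  SX <- colSums(Xz)
  SXX <- colSums(Xz^2)
  SXY <- crossprod(Xz, Y)
  Sxxc <- SXX - SX^2 / nj
  Sxyc <- SXY - (SX / nj) * SY
  Syyc <- SYY - SY^2 / nj
  eps <- 1e-12
  ok_x <- Sxxc > eps
  RSS1 <- Syyc - Sxyc^2 / pmax(Sxxc, eps)   # p-vector recycles per column
  RSS1[!ok_x, ] <- Syyc[!ok_x, ]
  lod <- (nj / 2) * log10(pmax(Syyc, eps) / pmax(RSS1, eps))
  lod[Syyc <= eps] <- 0
  lod <- pmin(lod, lod_max)
  lod[nj < min_n, ] <- NA_real_
  slope <- Sxyc / pmax(Sxxc, eps)
  slope[!ok_x, ] <- 0
  r2 <- 100 * (1 - RSS1 / pmax(Syyc, eps))
  r2[Syyc <= eps] <- 0
  list(lod = lod, effect = slope, r2 = r2, n = nj)
}

#' Single-marker LOD score with optional cofactors
#'
#' Regression-based (Haley-Knott style) test of one marker: the LOD score
#' is (n/2) log10(RSS0/RSS1) where the null model holds the intercept and
#' any cofactor markers and the alternative adds the test marker. The
#' additive effect is half the difference between the adjusted P1 and P2
#' genotype-class means; R-squared is the per-position variance fraction
#' 1 - RSS1/RSS0, in percent. Samples missing the phenotype, the test
#' marker or any cofactor are dropped.
#'
#' @param y numeric phenotype vector (binary traits coded 0/1).
#' @param x test-marker genotype codes 0/1/2/NA (P1/HET/P2/missing).
#' @param cofactors optional matrix of cofactor genotype codes.
#' @param lod_max cap for (near-)perfect fits (default 50).
#' @param min_n minimum informative samples, below which NA is returned
#'   (default 10).
#' @return list(LOD, effect, r2, n).
#' @export
lodAtMarker <- function(y, x, cofactors = NULL, lod_max = 50, min_n = 10L) {
  xc <- .markerCode(x)
  if (!is.null(cofactors)) {
    C <- apply(as.matrix(cofactors), 2, .markerCode)
    cc <- stats::complete.cases(y, xc, C)
  } else {
    C <- NULL
    cc <- stats::complete.cases(y, xc)
  }
  y <- y[cc]; xc <- xc[cc]
  n <- length(y)
  if (n < min_n) return(list(LOD = NA_real_, effect = NA_real_,
                             r2 = NA_real_, n = n))
  D0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C[cc, , drop = FALSE])
  f0 <- stats::lm.fit(D0, y)
  f1 <- stats::lm.fit(cbind(D0, xc), y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  eps <- 1e-12
  lod <- if (rss0 <= eps) 0 else
    min((n / 2) * log10(rss0 / max(rss1, eps)), lod_max)
  ry <- f0$residuals
  mP1 <- mean(ry[xc == 1]); mP2 <- mean(ry[xc == -1])
  effect <- if (is.finite(mP1) && is.finite(mP2)) (mP1 - mP2) / 2 else
    unname(f1$coefficients[ncol(D0) + 1L])
  r2 <- if (rss0 <= eps) 0 else 100 * (1 - rss1 / rss0)
  list(LOD = lod, effect = effect, r2 = r2, n = n)
}

#' Forward selection of background (cofactor) markers
#'
#' Greedy forward stepwise regression of the phenotype on bin markers:
#' at each step the marker with the smallest partial-F p-value is added,
#' stopping at \code{max_cofactors} or when the best candidate's p-value
#' exceeds \code{p_enter}. Missing marker codes are mean-imputed for the
#' selection only.
#'
#' @param y phenotype vector.
#' @param marker_matrix samples-by-markers genotype codes (0/1/2/NA).
#' @param max_cofactors maximum cofactors (default 5).
#' @param p_enter entry p-value threshold (default 0.01).
#' @return integer vector of selected marker column indices (may be empty).
#' @export
selectCofactors <- function(y, marker_matrix, max_cofactors = 5L,
                            p_enter = 0.01) {
  if (max_cofactors < 1L) return(integer())
  X <- apply(as.matrix(marker_matrix), 2, .markerCode)
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X))
  if (length(nas)) X[nas] <- cm[((nas - 1) %/% n) + 1L]
  selected <- integer()
  D <- matrix(1, n, 1)
  repeat {
    qrD <- qr(D)
    r <- qr.resid(qrD, y)
    rss_cur <- sum(r^2)
    Xt <- qr.resid(qrD, X)
    sxx <- colSums(Xt^2)
    gain <- ifelse(sxx > 1e-10, (crossprod(Xt, r)[, 1])^2 / sxx, 0)
    gain[selected] <- 0
    j <- which.max(gain)
    df2 <- n - ncol(D) - 1L
    if (df2 <= 0) break
    Fval <- gain[j] / ((rss_cur - gain[j]) / df2)
    pval <- stats::pf(Fval, 1, df2, lower.tail = FALSE)
    if (!is.finite(pval) || pval > p_enter) break
    selected <- c(selected, j)
    D <- cbind(D, X[, j])
    if (length(selected) >= max_cofactors) break
  }
  selected
}

#' Genome-wide LOD profile over bin markers
#'
#' Scans every bin marker with \code{\link{lodAtMarker}}, controlling
#' genetic background with forward-selected cofactors (composite interval
#' mapping style). Cofactors lying within \code{exclusion_window_cm} of
#' the test bin on the same chromosome are dropped from the model at that
#' position. With no cofactors the scan reduces to simple marker
#' regression and runs through a vectorised path.
#'
#' @param y named phenotype vector (names = sample ids).
#' @param linkage_map a \linkS4class{LinkageMap} over the same bins.
#' @param binmap a \linkS4class{BinMap}.
#' @param exclusion_window_cm cM window around the test bin from which
#'   cofactors are excluded (default 10).
#' @param max_cofactors maximum cofactors (default 5); 0 disables
#'   background control.
#' @param cofactors optional pre-selected cofactor bin indices.
#' @return data.frame with one row per bin: chrom, bin, pos_cM, pos_bp,
#'   LOD, effect, r2, n.
#' @export
genomeScan <- function(y, linkage_map, binmap, exclusion_window_cm = 10,
                       max_cofactors = 5L, cofactors = NULL) {
  m <- mapTable(linkage_map)
  geno <- genoCalls(binmap)
  stopifnot(nrow(m) == nrow(geno))
  common <- intersect(names(y), colnames(geno))
  if (length(common) == 0L) stop("no samples shared between y and the bin map")
  y <- y[common]
  ok <- !is.na(y)
  y <- y[ok]; common <- common[ok]
  G <- t(geno[, common, drop = FALSE])        # samples x bins
  if (is.null(cofactors) && max_cofactors > 0L)
    cofactors <- selectCofactors(y, G, max_cofactors)
  base <- data.frame(bin = m$bin, chrom = m$chrom,
                     pos_cM = m$cum_cM,
                     pos_bp = (m$start + m$end) / 2)
  if (length(cofactors) == 0L) {
    X <- apply(G, 2, .markerCode)
    sc <- .scanLODMatrix(X, y)
    return(cbind(base, LOD = sc$lod[, 1], effect = sc$effect[, 1],
                 r2 = sc$r2[, 1], n = sc$n))
  }
  res <- lapply(seq_len(nrow(m)), function(i) {
    near <- m$chrom[cofactors] == m$chrom[i] &
      abs(m$cum_cM[cofactors] - m$cum_cM[i]) < exclusion_window_cm
    use <- cofactors[!near & cofactors != i]
    co <- if (length(use)) G[, use, drop = FALSE] else NULL
    lodAtMarker(y, G[, i], co)
  })
  cbind(base,
        LOD = vapply(res, `[[`, numeric(1), "LOD"),
        effect = vapply(res, `[[`, numeric(1), "effect"),
        r2 = vapply(res, `[[`, numeric(1), "r2"),
        n = vapply(res, `[[`, numeric(1), "n"))
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype across samples, rescans the genome, and returns
#' the (1 - alpha) quantile of the permuted genome-wide maximum LOD.
#' Permutation scans use simple marker regression (no cofactors), the
#' standard choice for genome-wide thresholds.
#'
#' @param y named phenotype vector.
#' @param linkage_map,binmap as in \code{\link{genomeScan}}.
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed optional seed for the permutation stream.
#' @return LOD threshold (numeric scalar).
#' @export
permutationThreshold <- function(y, linkage_map, binmap, n_perm = 1000L,
                                 alpha = 0.05, seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  geno <- genoCalls(binmap)
  common <- intersect(names(y), colnames(geno))
  y <- y[common]
  ok <- !is.na(y)
  y <- y[ok]; common <- common[ok]
  X <- apply(t(geno[, common, drop = FALSE]), 2, .markerCode)
  .localSeed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    sc <- .scanLODMatrix(X, Y)
    maxima <- apply(sc$lod, 2, max, na.rm = TRUE)
    unname(stats::quantile(maxima, probs = 1 - alpha, type = 1))
  })
}

#' Call QTL peaks from a LOD profile
#'
#' Finds contiguous runs of bins with LOD above \code{lod_min}, splits a
#' run at internal local minima that drop at least \code{split_drop} LOD
#' below the flanking maxima, and reports each resulting peak with its
#' flanking bin markers (the bins adjacent to the peak bin) and the
#' corresponding physical interval. Peaks with R-squared at or below
#' \code{r2_min} percent are dropped.
#'
#' @param profile scan data.frame from \code{\link{genomeScan}}.
#' @param binmap the \linkS4class{BinMap} the profile was computed on.
#' @param lod_min LOD threshold (default 3, exclusive).
#' @param r2_min minimum phenotypic variance explained, percent
#'   (default 5, exclusive).
#' @param split_drop LOD drop required to split a run into several peaks
#'   (default 1).
#' @return data.frame of QTL peaks: chrom, peak bin, peak position (cM),
#'   flanking bins, map interval, physical interval and its length,
#'   LOD, additive effect, r2, and the span of the whole super-threshold
#'   region the peak belongs to.
#' @export
callQTL <- function(profile, binmap, lod_min = 3, r2_min = 5,
                    split_drop = 1) {
  gr <- rowRanges(binmap)
  out <- list()
  for (ch in unique(profile$chrom)) {
    pi <- which(profile$chrom == ch)
    lod <- profile$LOD[pi]
    above <- !is.na(lod) & lod > lod_min
    if (!any(above)) next
    runs <- rle(above)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    for (k in which(runs$values)) {
      seg <- run_start[k]:run_end[k]
      lseg <- lod[seg]
      # split at local minima that drop >= split_drop below both sides
      splits <- integer()
      if (length(seg) >= 3L) {
        for (i in 2:(length(seg) - 1L)) {
          lmax <- max(lseg[1:(i - 1L)])
          rmax <- max(lseg[(i + 1L):length(seg)])
          if (lseg[i] <= lmax - split_drop && lseg[i] <= rmax - split_drop &&
              lseg[i] <= lseg[i - 1L] && lseg[i] <= lseg[i + 1L])
            splits <- c(splits, i)
        }
      }
      bounds <- c(0L, splits, length(seg))
      for (b in seq_len(length(bounds) - 1L)) {
        sub <- seg[(bounds[b] + 1L):bounds[b + 1L]]
        # LOD saturates at its cap over strongly linked stretches; R2 is
        # monotone in LOD at fixed n but does not cap, so it breaks ties
        score <- lod[sub] + profile$r2[pi[sub]] * 1e-6
        peak_local <- sub[which.max(score)]
        i_global <- pi[peak_local]
        if (!is.na(profile$r2[i_global]) && profile$r2[i_global] <= r2_min)
          next
        i_lo <- pi[max(peak_local - 1L, 1L)]
        i_hi <- pi[min(peak_local + 1L, length(pi))]
        region <- pi[seg]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          peak_bin = profile$bin[i_global],
          peak_cM = profile$pos_cM[i_global],
          flank_left = profile$bin[i_lo],
          flank_right = profile$bin[i_hi],
          map_lo_cM = profile$pos_cM[i_lo],
          map_hi_cM = profile$pos_cM[i_hi],
          interval_start = start(gr)[i_lo],
          interval_end = end(gr)[i_hi],
          interval_bp = end(gr)[i_hi] - start(gr)[i_lo] + 1,
          LOD = profile$LOD[i_global],
          effect = profile$effect[i_global],
          r2 = profile$r2[i_global],
          region_start = start(gr)[region[1]],
          region_end = end(gr)[region[length(region)]],
          region_n_bins = length(region))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), peak_bin = character(),
               peak_cM = numeric(), flank_left = character(),
               flank_right = character(), map_lo_cM = numeric(),
               map_hi_cM = numeric(), interval_start = numeric(),
               interval_end = numeric(), interval_bp = numeric(),
               LOD = numeric(), effect = numeric(), r2 = numeric(),
               region_start = numeric(), region_end = numeric(),
               region_n_bins = integer())
}
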