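# Window genotype calling over one sample's ordered variant calls.
# Returns one call per window start index: GT_P1 / GT_P2 if that parent
# exceeds `cutoff` of the non-missing calls in the window, GT_HET
# otherwise; windows with fewer than `min_informative` non-missing calls
# are deferred to the nearest informative window's call.
.windowCallVec <- function(calls, window_size, cutoff, min_informative) {
  n <- length(calls)
  nP1 <- .slidingSum(!is.na(calls) & calls == GT_P1, window_size)
  nP2 <- .slidingSum(!is.na(calls) & calls == GT_P2, window_size)
  inf <- .slidingSum(!is.na(calls), window_size)
  wc <- rep(GT_HET, n - window_size + 1L)
  wc[nP1 > cutoff * inf] <- GT_P1
  wc[nP2 > cutoff * inf] <- GT_P2
  wc[inf < min_informative] <- NA_integer_
  .fillNearest(wc)
}

#' Call sliding-window genotypes for one sample on one chromosome
#'
#' Slides a window of \code{window_size} consecutive retained variants,
#' advancing one variant at a time, and calls each window P1 or P2 when
#' more than \code{cutoff} (70 percent by default) of its non-missing
#' calls agree with that parent, heterozygous otherwise. Windows with
#' fewer than \code{min_informative} non-missing calls take the nearest
#' informative window's call. A chromosome with fewer variants than the
#' window is reduced to a single whole-chromosome majority call, with a
#' warning.
#'
#' @param calls integer vector of one sample's calls (0/1/2/NA) in
#'   physical order.
#' @param positions variant positions (bp), same length and order.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param window_size variants per window (default 15).
#' @param cutoff consistency fraction required for a parental call
#'   (default 0.7, exclusive).
#' @param min_informative minimum non-missing calls for a window to be
#'   called directly (default 5).
#' @return object of class \code{window_calls}: a list with the window
#'   table (\code{first}/\code{last} variant index, bp span, genotype
#'   code) and the inputs needed by \code{\link{resolveBreakpoints}}.
#' @export
callWindows <- function(calls, positions, chrom, chrom_length,
                        window_size = 15L, cutoff = 0.7,
                        min_informative = 5L) {
  n <- length(calls)
  stopifnot(n == length(positions))
  if (n < window_size) {
    warning("chromosome ", chrom, " has ", n, " variants (< window size ",
            window_size, "); using whole-chromosome majority call")
    n0 <- sum(calls == GT_P1, na.rm = TRUE)
    n2 <- sum(calls == GT_P2, na.rm = TRUE)
    wc <- if (n0 > n2) GT_P1 else if (n2 > n0) GT_P2 else GT_HET
    windows <- data.frame(first = 1L, last = n, start_bp = positions[1],
                          end_bp = positions[n], genotype = wc)
  } else {
    wc <- .windowCallVec(calls, window_size, cutoff, min_informative)
    first <- seq_along(wc)
    last <- first + window_size - 1L
    windows <- data.frame(first = first, last = last,
                          start_bp = positions[first],
                          end_bp = positions[last], genotype = wc)
  }
  structure(list(windows = windows, positions = positions, chrom = chrom,
                 chrom_length = chrom_length, window_size = window_size,
                 cutoff = cutoff, n_variants = n),
            class = "window_calls")
}

# Smooth runs of < min_run identical window calls whose two flanking runs
# agree with each other; repeated until stable.
.smoothRuns <- function(wc, min_run) {
  if (min_run <= 1L || length(wc) < 3L) return(wc)
  for (iter in 1:5) {
    key <- ifelse(is.na(wc), -1L, wc)
    r <- rle(key)
    if (length(r$lengths) < 3L) break
    changed <- FALSE
    for (i in 2:(length(r$lengths) - 1L)) {
      if (r$lengths[i] < min_run && r$values[i - 1] == r$values[i + 1] &&
          r$values[i] != r$values[i - 1]) {
        r$values[i] <- r$values[i - 1]
        changed <- TRUE
      }
    }
    wc <- inverse.rle(r)
    wc[wc == -1L] <- NA_integer_
    if (!changed) break
  }
  wc
}

#' Resolve recombination breakpoints from window calls
#'
#' Merges consecutive identical window calls into genotype segments and
#' emits a breakpoint at every genotype transition. Each variant is first
#' assigned the call of the window centred on it; short runs (fewer than
#' \code{min_run} windows) flanked by agreeing genotypes are smoothed
#' away; and the short heterozygous-looking transition zone that a clean
#' homozygous-to-homozygous crossover necessarily produces (no parent can
#' exceed the 70 percent cutoff across the crossover) is collapsed into
#' the breakpoint when it spans fewer than \code{window_size} variants.
#' The breakpoint point estimate is the midpoint between the last variant
#' supporting the left genotype and the first supporting the right; those
#' two variant positions are the flank bounds.
#'
#' @param wc a \code{window_calls} object from \code{\link{callWindows}}.
#' @param min_run minimum run of identical window calls kept before
#'   smoothing (default 3).
#' @return list with \code{segments} (bp-tiling data.frame: chrom, start,
#'   end, genotype) and \code{breakpoints} (chrom, pos, flank_lo,
#'   flank_hi, from_genotype, to_genotype).
#' @export
resolveBreakpoints <- function(wc, min_run = 3L) {
  pos <- wc$positions
  n <- wc$n_variants
  w <- wc$window_size
  L <- wc$chrom_length
  empty_bp <- data.frame(chrom = character(), pos = numeric(),
                         flank_lo = numeric(), flank_hi = numeric(),
                         from_genotype = integer(), to_genotype = integer())
  if (n < w) {
    seg <- data.frame(chrom = wc$chrom, start = 1, end = L,
                      genotype = wc$windows$genotype[1])
    return(list(segments = seg, breakpoints = empty_bp))
  }
  wcalls <- .smoothRuns(wc$windows$genotype, min_run)
  # per-variant consensus: call of the window centred on the variant
  ctr <- pmin(pmax(seq_len(n) - (w - 1L) %/% 2L, 1L), length(wcalls))
  a <- wcalls[ctr]
  key <- ifelse(is.na(a), -1L, a)
  r <- rle(key)
  vend <- cumsum(r$lengths)
  vstart <- vend - r$lengths + 1L
  gt <- ifelse(r$values == -1L, NA_integer_, r$values)
  # collapse short HET transition zones between two different homozygotes
  keep <- rep(TRUE, length(gt))
  if (length(gt) >= 3L) {
    for (i in 2:(length(gt) - 1L)) {
      if (!is.na(gt[i]) && gt[i] == GT_HET && r$lengths[i] < w &&
          !is.na(gt[i - 1]) && !is.na(gt[i + 1]) &&
          gt[i - 1] != GT_HET && gt[i + 1] != GT_HET &&
          gt[i - 1] != gt[i + 1])
        keep[i] <- FALSE
    }
  }
  gt <- gt[keep]; vstart <- vstart[keep]; vend <- vend[keep]
  # merge any adjacent equal genotypes created by the collapse
  if (length(gt) > 1L) {
    same <- c(FALSE, gt[-1] == gt[-length(gt)] & !is.na(gt[-1]) &
                !is.na(gt[-length(gt)]))
    first_idx <- which(!same)
    last_idx <- c(first_idx[-1] - 1L, length(gt))
    vstart <- vstart[first_idx]
    vend <- vend[last_idx]
    gt <- gt[first_idx]
  }
  ns <- length(gt)
  if (ns == 1L) {
    seg <- data.frame(chrom = wc$chrom, start = 1, end = L, genotype = gt)
    return(list(segments = seg, breakpoints = empty_bp))
  }
  # At a homozygote/heterozygote boundary the window consensus flips once
  # the heterozygous content exceeds 1 - cutoff, i.e. w*(cutoff - 0.5)
  # variants before the true boundary on the heterozygous side; pad the
  # flank on that side so the bound still brackets the true junction.
  pad <- as.integer(ceiling(w * (wc$cutoff - 0.5))) + 2L
  lo_idx <- vend[-ns]
  hi_idx <- vstart[-1]
  left_gt <- gt[-ns]; right_gt <- gt[-1]
  het_right <- !is.na(right_gt) & right_gt == GT_HET
  het_left <- !is.na(left_gt) & left_gt == GT_HET
  hi_idx[het_right] <- pmin(hi_idx[het_right] + pad, vend[-1][het_right])
  lo_idx[het_left] <- pmax(lo_idx[het_left] - pad, vstart[-ns][het_left])
  flank_lo <- pos[lo_idx]
  flank_hi <- pos[hi_idx]
  bp_pos <- floor((flank_lo + flank_hi) / 2)
  breakpoints <- data.frame(chrom = wc$chrom, pos = bp_pos,
                            flank_lo = flank_lo, flank_hi = flank_hi,
                            from_genotype = gt[-ns], to_genotype = gt[-1])
  segments <- data.frame(chrom = wc$chrom,
                         start = c(1, bp_pos + 1),
                         end = c(bp_pos, L),
                         genotype = gt)
  list(segments = segments, breakpoints = breakpoints)
}

#' Partition the genome into population-level bins
#'
#' Bin boundaries are the sorted union of every sample's breakpoint point
#' estimates plus the chromosome ends, so that no sample has a breakpoint
#' strictly inside a bin. Each bin carries every sample's segment
#' genotype; adjacent bins with identical genotype columns across all
#' samples are merged.
#'
#' @param sample_segments named list (one element per sample) of segment
#'   data.frames as returned by \code{\link{resolveBreakpoints}} (rows
#'   from several chromosomes may be bound together).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return a \linkS4class{BinMap}.
#' @export
buildPopulationBins <- function(sample_segments, chrom_lengths) {
  if (length(sample_segments) < 2L)
    stop("need segment maps for at least 2 samples")
  samples <- names(sample_segments)
  chroms <- names(chrom_lengths)
  bin_rows <- list(); geno_rows <- list()
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    per <- lapply(sample_segments, function(s) s[s$chrom == ch, , drop = FALSE])
    ends <- sort(unique(c(unlist(lapply(per, function(s) s$end)), L)))
    ends <- ends[ends <= L]
    if (length(ends) == 0L || ends[length(ends)] != L) ends <- c(ends, L)
    starts <- c(1, head(ends, -1) + 1)
    geno <- matrix(NA_integer_, nrow = length(ends), ncol = length(samples),
                   dimnames = list(NULL, samples))
    for (si in seq_along(per)) {
      s <- per[[si]]
      if (nrow(s) == 0L) next
      idx <- findInterval(starts, s$start)
      ok <- idx >= 1L & idx <= nrow(s)
      geno[ok, si] <- s$genotype[idx[ok]]
    }
    # merge adjacent bins identical across all samples
    if (length(ends) > 1L) {
      keyN <- apply(geno, 1, function(z) paste(ifelse(is.na(z), ".", z),
                                               collapse = ""))
      new_grp <- c(TRUE, keyN[-1] != keyN[-length(keyN)])
      first_idx <- which(new_grp)
      last_idx <- c(first_idx[-1] - 1L, length(ends))
      starts <- starts[first_idx]
      ends <- ends[last_idx]
      geno <- geno[new_grp, , drop = FALSE]
    }
    bin_rows[[ch]] <- data.frame(chrom = ch, start = as.numeric(starts),
                                 end = as.numeric(ends))
    geno_rows[[ch]] <- geno
  }
  bins <- do.call(rbind, bin_rows)
  geno <- do.call(rbind, geno_rows)
  gr <- GRanges(bins$chrom, IRanges(bins$start, bins$end),
                seqinfo = Seqinfo(chroms, unname(unlist(chrom_lengths))))
  names(gr) <- sprintf("%s_bin%d", bins$chrom,
                       stats::ave(rep(1L, nrow(bins)), bins$chrom,
                                  FUN = seq_along))
  se <- SummarizedExperiment(assays = list(geno = geno), rowRanges = gr)
  new("BinMap", se)
}

#' Build a bin map from a population genotype matrix
#'
#' Runs \code{\link{callWindows}} and \code{\link{resolveBreakpoints}} for
#' every sample and chromosome, then assembles the population bin map.
#'
#' @param genotypes a \linkS4class{RilGenotypes} of filtered, polarized
#'   calls.
#' @param window_size,cutoff,min_informative see \code{\link{callWindows}}.
#' @param min_run see \code{\link{resolveBreakpoints}}.
#' @return list with \code{binmap} (a \linkS4class{BinMap}) and
#'   \code{breakpoints} (per-sample breakpoint table).
#' @export
binMarkers <- function(genotypes, window_size = 15L, cutoff = 0.7,
                       min_run = 3L, min_informative = 5L) {
  v <- genoCalls(genotypes)
  gr <- rowRanges(genotypes)
  chroms <- seqlevels(gr)
  lens <- seqlengths(gr)
  if (anyNA(lens))
    lens[is.na(lens)] <- vapply(chroms[is.na(lens)], function(ch)
      max(end(gr[seqnames(gr) == ch])), numeric(1))
  chr_of <- as.character(seqnames(gr))
  pos_of <- start(gr)
  idx_by_chr <- split(seq_along(gr), chr_of)[chroms]
  samples <- colnames(v)
  seg_list <- stats::setNames(vector("list", length(samples)), samples)
  bp_list <- list()
  for (si in seq_along(samples)) {
    segs <- list()
    for (ch in chroms) {
      idx <- idx_by_chr[[ch]]
      if (is.null(idx) || length(idx) == 0L) next
      wc <- suppressWarnings(
        callWindows(v[idx, si], pos_of[idx], ch, lens[[ch]],
                    window_size, cutoff, min_informative))
      res <- resolveBreakpoints(wc, min_run)
      segs[[ch]] <- res$segments
      if (nrow(res$breakpoints))
        bp_list[[length(bp_list) + 1L]] <-
          cbind(sample = samples[si], res$breakpoints)
    }
    seg_list[[si]] <- do.call(rbind, segs)
  }
  breakpoints <- if (length(bp_list)) do.call(rbind, bp_list) else
    data.frame(sample = character(), chrom = character(), pos = numeric(),
               flank_lo = numeric(), flank_hi = numeric(),
               from_genotype = integer(), to_genotype = integer())
  binmap <- buildPopulationBins(seg_list, as.list(lens[chroms]))
  list(binmap = binmap, breakpoints = breakpoints, segments = seg_list)
}
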