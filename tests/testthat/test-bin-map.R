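# Brute-force window scorer used as oracle for the sliding implementation.
bruteWindows <- function(calls, w = 15, cutoff = 0.7) {
  n <- length(calls)
  vapply(seq_len(n - w + 1), function(j) {
    win <- calls[j:(j + w - 1)]
    inf <- sum(!is.na(win))
    nP1 <- sum(win == 0L, na.rm = TRUE)
    nP2 <- sum(win == 2L, na.rm = TRUE)
    if (inf < 5) return(NA_integer_)
    if (nP1 > cutoff * inf) 0L else if (nP2 > cutoff * inf) 2L else 1L
  }, integer(1))
}

test_that("window genotype rule follows the 70 percent consistency cutoff", {
  pos <- seq_len(15) * 1000
  w1 <- callWindows(c(rep(0L, 11), rep(2L, 4)), pos, "Chr1", 2e4)
  expect_equal(w1$windows$genotype, 0L)           # 11/15 = 73.3% > 70%
  w2 <- callWindows(c(rep(0L, 10), rep(2L, 5)), pos, "Chr1", 2e4)
  expect_equal(w2$windows$genotype, 1L)           # 66.7% both ways -> HET
  w3 <- callWindows(c(rep(0L, 9), rep(2L, 3), rep(NA_integer_, 3)),
                    pos, "Chr1", 2e4)
  expect_equal(w3$windows$genotype, 0L)           # 9/12 = 75% of non-missing
})

test_that("sliding windows agree with the brute-force scorer", {
  set.seed(42)
  for (rep in 1:5) {
    calls <- sample(c(0L, 1L, 2L, NA_integer_), 200, replace = TRUE,
                    prob = c(0.45, 0.05, 0.45, 0.05))
    wc <- callWindows(calls, seq_len(200) * 500, "Chr1", 2e5)
    oracle <- bruteWindows(calls)
    got <- wc$windows$genotype
    # deferred (low-information) windows take a neighbour's call; compare
    # only directly-called windows
    expect_equal(got[!is.na(oracle)], oracle[!is.na(oracle)])
  }
})

test_that("uniform genotype yields one segment and no breakpoints", {
  wc <- callWindows(rep(0L, 50), seq_len(50) * 1000, "Chr1", 60000)
  res <- resolveBreakpoints(wc)
  expect_equal(nrow(res$breakpoints), 0)
  expect_equal(res$segments$start, 1)
  expect_equal(res$segments$end, 60000)
  expect_equal(res$segments$genotype, 0L)
})

test_that("breakpoint is the midpoint of its flanking variants", {
  # clean P1 run then P2 run; flanking variants at 1,000,000 / 1,001,000
  pos <- c(seq(970000, 1000000, by = 1000), seq(1001000, 1031000, by = 1000))
  calls <- c(rep(0L, 31), rep(2L, 31))
  wc <- callWindows(calls, pos, "Chr1", 2e6)
  res <- resolveBreakpoints(wc)
  expect_equal(nrow(res$breakpoints), 1)
  bp <- res$breakpoints
  expect_equal(bp$pos, 1000500)
  expect_lt(bp$flank_lo, bp$pos)
  expect_gte(bp$flank_hi, bp$pos)
  expect_true(bp$flank_lo < 1000500 && bp$flank_hi >= 1000500)
  expect_equal(bp$from_genotype, 0L)
  expect_equal(bp$to_genotype, 2L)
  # segments tile around the breakpoint
  expect_equal(res$segments$start, c(1, bp$pos + 1))
  expect_equal(res$segments$end, c(bp$pos, 2e6))
})

test_that("short chromosomes fall back to a majority call with warning", {
  expect_warning(
    wc <- callWindows(c(0L, 0L, 2L), c(100, 200, 300), "Chr1", 1000),
    "majority")
  res <- resolveBreakpoints(wc)
  expect_equal(res$segments$genotype, 0L)
})

test_that("noise-free simulated crossovers are recovered within flanks", {
  cfg <- twoChromConfig(n_rils = 40, n_variants = 1000, seed = 17,
                        missing_rate = 0, error_rate = 0,
                        het_call_rate = 0, causal = NULL)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  xo <- st$truth$crossovers
  gr <- siteRanges(st$genotypes)
  pos_by <- split(GenomicRanges::start(gr),
                  as.character(GenomicRanges::seqnames(gr)))
  eligible <- recovered <- 0
  for (i in seq_len(nrow(xo))) {
    b <- bm$breakpoints[bm$breakpoints$sample == xo$ril[i] &
                          bm$breakpoints$chrom == xo$chrom[i], ]
    pos <- pos_by[[xo$chrom[i]]]
    others <- xo[xo$ril == xo$ril[i] & xo$chrom == xo$chrom[i], "pos"]
    others <- setdiff(others, xo$pos[i])
    mi <- findInterval(xo$pos[i], pos)
    sep <- if (length(others)) min(abs(mi - findInterval(others, pos)))
           else Inf
    if (sep < 30) next
    eligible <- eligible + 1
    if (any(b$flank_lo < xo$pos[i] & xo$pos[i] <= b$flank_hi))
      recovered <- recovered + 1
  }
  expect_gt(eligible, 20)
  expect_gte(recovered / eligible, 0.95)
})

test_that("population bins are the union of sample breakpoints", {
  segA <- data.frame(chrom = "Chr1", start = c(1, 10001),
                     end = c(10000, 30000), genotype = c(0L, 2L))
  segB <- data.frame(chrom = "Chr1", start = c(1, 20001),
                     end = c(20000, 30000), genotype = c(0L, 2L))
  bm <- buildPopulationBins(list(A = segA, B = segB),
                            list(Chr1 = 30000))
  gr <- siteRanges(bm)
  expect_equal(GenomicRanges::start(gr), c(1, 10001, 20001))
  expect_equal(GenomicRanges::end(gr), c(10000, 20000, 30000))
  geno <- genoCalls(bm)
  expect_equal(unname(geno[, "A"]), c(0L, 2L, 2L))
  expect_equal(unname(geno[, "B"]), c(0L, 0L, 2L))
})

test_that("a recombination-free population collapses to one bin per chromosome", {
  seg <- data.frame(chrom = "Chr1", start = 1, end = 5e4, genotype = 0L)
  seg2 <- seg; seg2$genotype <- 2L
  bm <- buildPopulationBins(list(A = seg, B = seg2), list(Chr1 = 5e4))
  expect_equal(nrow(bm), 1L)
})

test_that("bin count equals distinct breakpoints plus chromosomes and bins tile", {
  cfg <- twoChromConfig(n_rils = 60, n_variants = 800, seed = 23,
                        missing_rate = 0, error_rate = 0,
                        het_call_rate = 0, causal = NULL)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  n_distinct <- length(unique(paste(bm$breakpoints$chrom,
                                    bm$breakpoints$pos)))
  expect_equal(nrow(bm$binmap), n_distinct + 2L)
  # tiling per chromosome
  gr <- siteRanges(bm$binmap)
  for (ch in c("Chr1", "Chr2")) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    g <- g[order(GenomicRanges::start(g))]
    expect_equal(GenomicRanges::start(g)[1], 1)
    expect_equal(GenomicRanges::end(g)[length(g)], 3e6)
    if (length(g) > 1)
      expect_equal(GenomicRanges::start(g)[-1],
                   head(GenomicRanges::end(g), -1) + 1)
  }
  # reconstruction: bin genotypes reproduce each sample's segment map
  geno <- genoCalls(bm$binmap)
  for (s in sample(colnames(geno), 5)) {
    seg <- bm$segments[[s]]
    mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
    expected <- vapply(seq_along(gr), function(i) {
      ss <- seg[seg$chrom == as.character(GenomicRanges::seqnames(gr))[i], ]
      ss$genotype[ss$start <= mid[i] & ss$end >= mid[i]][1]
    }, integer(1))
    expect_equal(unname(geno[, s]), expected)
  }
})

test_that("false breakpoints are rare at 2 percent genotyping error", {
  cfg <- twoChromConfig(n_rils = 60, n_variants = 1000, seed = 29,
                        missing_rate = 0, error_rate = 0.02,
                        het_call_rate = 0, causal = NULL)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  xo <- st$truth$crossovers
  # a detected breakpoint is false when no true crossover of that sample
  # lies within 150 kb
  false_n <- 0
  for (i in seq_len(nrow(bm$breakpoints))) {
    b <- bm$breakpoints[i, ]
    truth <- xo[xo$ril == b$sample & xo$chrom == b$chrom, "pos"]
    if (!length(truth) || min(abs(truth - b$pos)) > 150000)
      false_n <- false_n + 1
  }
  expect_lt(false_n / (60 * 2), 0.1)
})
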