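test_that("parent catalog is informative, ordered and deterministic", {
  cfg <- simConfig(chromosomes = data.frame(name = "Chr1", length_bp = 1e6,
                                            length_morgans = 0.5),
                   n_variants = 100, n_rils = 10, causal_loci = NULL,
                   seed = 7)
  cat1 <- simulateParents(cfg)
  expect_length(cat1, 100)
  expect_false(is.unsorted(GenomicRanges::start(cat1), strictly = TRUE))
  p1 <- S4Vectors::mcols(cat1)$p1_call
  p2 <- S4Vectors::mcols(cat1)$p2_call
  expect_true(all(p1 %in% c("HOM_REF", "HOM_ALT")))
  expect_true(all(p1 != p2))
  cat2 <- simulateParents(cfg)
  expect_identical(as.data.frame(cat2), as.data.frame(cat1))
})

test_that("per-chromosome catalog sizes follow the requested density", {
  lens <- c(42145699, 49200776, 50652576, 40408058, 47253416, 36015257,
            35964515, 40690061, 58970518)
  counts <- c(467, 1402, 7983, 403, 3687, 2983, 1225, 15315, 12558)
  cfg <- simConfig(chromosomes = data.frame(name = paste0("Chr", 1:9),
                                            length_bp = lens,
                                            length_morgans = rep(1.5, 9)),
                   n_variants = counts, n_rils = 10, causal_loci = NULL,
                   seed = 1)
  cat <- simulateParents(cfg)
  got <- table(as.character(GenomicRanges::seqnames(cat)))[paste0("Chr", 1:9)]
  expect_equal(unname(as.integer(got)), counts)
  expect_equal(sum(got), 46023)
})

test_that("residual heterozygosity decays as (1/2)^g", {
  cfg <- twoChromConfig(n_rils = 200, n_variants = 400, seed = 21,
                        missing_rate = 0, error_rate = 0, het_call_rate = 0,
                        causal = NULL)
  sim <- simulateRils(cfg, simulateParents(cfg))
  v <- genoCalls(sim$genotypes)
  phet <- mean(v == 1L)
  expected <- 0.5^6
  sigma <- sqrt(expected * (1 - expected) / length(v)) * 20  # site LD inflates
  expect_lt(abs(phet - expected), 0.01)
  # Mendelian symmetry: P1 allele frequency near 0.5
  expect_lt(abs(mean(v == 0L) - mean(v == 2L)), 0.08)
})

test_that("true segments tile each chromosome exactly", {
  cfg <- twoChromConfig(n_rils = 20, n_variants = 50, seed = 4,
                        causal = NULL)
  sim <- simulateRils(cfg, simulateParents(cfg))
  segs <- sim$truth$segments
  for (key in unique(paste(segs$ril, segs$chrom))) {
    p <- strsplit(key, " ")[[1]]
    s <- segs[segs$ril == p[1] & segs$chrom == p[2], ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 1)
    expect_equal(s$end[nrow(s)], 3e6)
    if (nrow(s) > 1)
      expect_equal(s$start[-1], head(s$end, -1) + 1)
  }
})

test_that("zero genetic length gives whole-chromosome parental lines", {
  cfg <- simConfig(chromosomes = data.frame(name = "Chr1", length_bp = 1e6,
                                            length_morgans = 0),
                   n_variants = 100, n_rils = 50, causal_loci = NULL,
                   seed = 2)
  sim <- simulateRils(cfg, simulateParents(cfg))
  expect_equal(nrow(sim$truth$crossovers), 0)
  v <- genoCalls(sim$genotypes)
  expect_true(all(apply(v, 2, function(col) length(unique(col)) == 1)))
})

test_that("end-to-end recombinant fraction matches Haldane-Waddington", {
  # 1-Morgan chromosome: r across the ends is 0.5(1 - exp(-2)) under the
  # Poisson model; at (near) fixation R = 2r/(1+2r)
  cfg <- simConfig(chromosomes = data.frame(name = "Chr1", length_bp = 1e7,
                                            length_morgans = 1),
                   n_variants = 50, n_rils = 400, selfing_generations = 12,
                   missing_rate = 0, error_rate = 0, het_call_rate = 0,
                   causal_loci = NULL, seed = 13)
  sim <- simulateRils(cfg, simulateParents(cfg))
  v <- genoCalls(sim$genotypes)
  a <- v[1, ]; b <- v[nrow(v), ]
  hom <- a != 1L & b != 1L
  R_obs <- mean(a[hom] != b[hom])
  r <- 0.5 * (1 - exp(-2))
  R_expected <- 2 * r / (1 + 2 * r)
  expect_lt(abs(R_obs - R_expected), 0.08)
})

test_that("observation noise hits its configured rates", {
  cfg <- twoChromConfig(n_rils = 50, n_variants = 500, seed = 8,
                        missing_rate = 0.3, causal = NULL)
  sim <- simulateRils(cfg, simulateParents(cfg))
  obs <- observeGenotypes(sim$genotypes, cfg)
  missf <- mean(is.na(genoCalls(obs)))
  expect_lt(abs(missf - 0.3), 0.01)

  cfg0 <- twoChromConfig(n_rils = 20, n_variants = 100, seed = 8,
                         missing_rate = 0, error_rate = 0,
                         het_call_rate = 0, causal = NULL)
  sim0 <- simulateRils(cfg0, simulateParents(cfg0))
  obs0 <- observeGenotypes(sim0$genotypes, cfg0)
  expect_identical(genoCalls(obs0), genoCalls(sim0$genotypes))

  cfg1 <- twoChromConfig(n_rils = 10, n_variants = 100, seed = 8,
                         missing_rate = 1, causal = NULL)
  sim1 <- simulateRils(cfg1, simulateParents(cfg1))
  expect_true(all(is.na(genoCalls(observeGenotypes(sim1$genotypes, cfg1)))))
})

test_that("phenotypes follow causal genotypes with configured penetrance", {
  cfg <- twoChromConfig(n_rils = 400, n_variants = 100, seed = 31,
                        causal = data.frame(chrom = "Chr1", pos = 1.5e6,
                                            trait = "AC", penetrance = 1))
  sim <- simulateRils(cfg, simulateParents(cfg))
  ph <- assignPhenotypes(sim$truth, cfg)
  cm <- traitCorrelations(ph)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 1) < 1e-12))
  base <- ifelse(sim$truth$causal_geno[, "AC"] == 0L, 0L, 1L)
  e1 <- ph[ph$environment == "18CD", ]
  expect_equal(e1$value[match(rownames(sim$truth$causal_geno), e1$sample)],
               unname(base))

  cfg95 <- twoChromConfig(n_rils = 400, n_variants = 100, seed = 31,
                          causal = data.frame(chrom = "Chr1", pos = 1.5e6,
                                              trait = "AC",
                                              penetrance = 0.95))
  sim95 <- simulateRils(cfg95, simulateParents(cfg95))
  ph95 <- assignPhenotypes(sim95$truth, cfg95)
  base95 <- ifelse(sim95$truth$causal_geno[, "AC"] == 0L, 0L, 1L)
  e1 <- ph95[ph95$environment == "18CD", ]
  disc <- mean(e1$value[match(rownames(sim95$truth$causal_geno),
                              e1$sample)] != base95)
  expect_lt(abs(disc - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("causal loci outside the genome are rejected", {
  expect_error(
    twoChromConfig(causal = data.frame(chrom = "Chr1", pos = 9e6,
                                       trait = "AC", penetrance = 0.97)),
    "outside")
  expect_error(
    twoChromConfig(causal = data.frame(chrom = "Chr9", pos = 100,
                                       trait = "AC", penetrance = 0.97)),
    "unknown")
})

test_that("whole-study simulation is byte-deterministic under a seed", {
  cfg <- twoChromConfig(n_rils = 30, n_variants = 200, seed = 12)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(genoCalls(s1$genotypes), genoCalls(s2$genotypes))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$crossovers, s2$truth$crossovers)
})
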