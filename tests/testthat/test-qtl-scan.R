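# Hand least-squares LOD via explicit normal equations: the independent
# oracle for lodAtMarker.
handLOD <- function(y, x, C = NULL) {
  keep <- stats::complete.cases(y, x, C)
  y <- y[keep]; x <- x[keep]
  D0 <- matrix(1, length(y), 1)
  if (!is.null(C)) D0 <- cbind(D0, C[keep, , drop = FALSE])
  b0 <- solve(t(D0) %*% D0, t(D0) %*% y)
  rss0 <- sum((y - D0 %*% b0)^2)
  D1 <- cbind(D0, x)
  b1 <- solve(t(D1) %*% D1, t(D1) %*% y)
  rss1 <- sum((y - D1 %*% b1)^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

test_that("trait correlations reproduce the expected patterns", {
  ph <- data.frame(sample = rep(sprintf("S%02d", 1:20), 2),
                   trait = "AC",
                   environment = rep(c("E1", "E2"), each = 20),
                   value = rep(c(rep(0, 10), rep(1, 10)), 2))
  cm <- traitCorrelations(ph)
  expect_equal(cm["ACE1", "ACE2"], 1)
  ph$value[ph$environment == "E2"] <- 1 - ph$value[ph$environment == "E2"]
  expect_equal(traitCorrelations(ph)["ACE1", "ACE2"], -1)
  # independent traits decorrelate at n = 400
  set.seed(77)
  ph2 <- rbind(
    data.frame(sample = sprintf("S%03d", 1:400), trait = "AC",
               environment = "E1", value = rbinom(400, 1, 0.5)),
    data.frame(sample = sprintf("S%03d", 1:400), trait = "HC",
               environment = "E1", value = rbinom(400, 1, 0.5)))
  expect_lt(abs(traitCorrelations(ph2)["ACE1", "HCE1"]), 0.15)
  # zero-variance column gives NA
  ph3 <- ph2
  ph3$value[ph3$trait == "HC"] <- 1
  expect_true(is.na(traitCorrelations(ph3)["ACE1", "HCE1"]))
})

test_that("the 8-sample hand example gives LOD 0.500", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  # dummy 1/0 mapped onto additive codes: 1 -> P1 (0), 0 -> P2 (2)
  x <- c(0L, 0L, 0L, 2L, 0L, 2L, 2L, 2L)
  res <- lodAtMarker(y, x, min_n = 5)
  expect_equal(res$LOD, 4 * log10(4 / 3), tolerance = 1e-12)
  expect_equal(res$LOD, 0.500, tolerance = 1e-3)
})

test_that("a perfectly predictive marker caps LOD with full R-squared", {
  x <- rep(c(0L, 2L), each = 50)
  y <- rep(c(0, 1), each = 50)
  res <- lodAtMarker(y, x)
  expect_equal(res$LOD, 50)
  expect_equal(res$r2, 100)
  expect_equal(abs(res$effect), 0.5)
})

test_that("LOD is invariant to phenotype label swap; effect flips sign", {
  set.seed(5)
  x <- sample(c(0L, 1L, 2L, NA), 120, replace = TRUE,
              prob = c(0.45, 0.05, 0.45, 0.05))
  y <- rbinom(120, 1, ifelse(is.na(x), 0.5, 0.2 + 0.3 * (x == 2L)))
  a <- lodAtMarker(y, x)
  b <- lodAtMarker(1 - y, x)
  expect_equal(a$LOD, b$LOD, tolerance = 1e-12)
  expect_equal(a$effect, -b$effect, tolerance = 1e-12)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
})

test_that("lodAtMarker and the vectorised scan match hand least-squares", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 40
    x <- sample(c(0L, 2L), n, replace = TRUE)
    y <- rbinom(n, 1, 0.3 + 0.4 * (x == 0L))
    if (var(y) == 0 || length(unique(x)) < 2) next
    expect_equal(lodAtMarker(y, x)$LOD, handLOD(y, 1 - as.numeric(x)),
                 tolerance = 1e-8)
    # with a random cofactor
    co <- sample(c(0L, 2L), n, replace = TRUE)
    if (length(unique(co)) < 2 || all(co == x) || all(co != x)) next
    expect_equal(lodAtMarker(y, x, cofactors = cbind(co))$LOD,
                 handLOD(y, 1 - as.numeric(x),
                         C = cbind(1 - as.numeric(co))),
                 tolerance = 1e-8)
    # vectorised path
    X <- matrix(1 - as.numeric(x), ncol = 1)
    sc <- iraQTL:::.scanLODMatrix(X, matrix(y, ncol = 1))
    expect_equal(sc$lod[1, 1], handLOD(y, X[, 1]), tolerance = 1e-8)
  }
})

test_that("an uninformative marker gives LOD near zero, few samples give NA", {
  set.seed(2)
  y <- rbinom(200, 1, 0.5)
  x <- sample(c(0L, 2L), 200, replace = TRUE)
  expect_lt(lodAtMarker(y, x)$LOD, 2)
  expect_true(is.na(lodAtMarker(y[1:5], x[1:5])$LOD))
})

test_that("cofactor selection finds the causal bin and ignores pure noise", {
  cfg <- twoChromConfig(n_rils = 200, n_variants = 400, seed = 6)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  ph <- st$phenotypes[st$phenotypes$trait == "AC" &
                        st$phenotypes$environment == "18CD", ]
  y <- stats::setNames(ph$value, ph$sample)
  G <- t(genoCalls(bm$binmap)[, names(y)])
  sel <- selectCofactors(y, G)
  expect_gt(length(sel), 0)
  gr <- siteRanges(bm$binmap)
  first <- gr[sel[1]]
  expect_equal(as.character(GenomicRanges::seqnames(first)), "Chr1")
  expect_lt(min(abs(c(GenomicRanges::start(first),
                      GenomicRanges::end(first)) - 1.5e6)), 5e5)
  expect_equal(length(selectCofactors(y, G, max_cofactors = 0)), 0)
  # pure-noise phenotype: rarely any cofactor at p = 0.01
  set.seed(33)
  hits <- vapply(1:10, function(i) {
    yn <- stats::setNames(rbinom(nrow(G), 1, 0.5), rownames(G))
    length(selectCofactors(yn, G))
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.5)
})

test_that("genome scan peaks at the causal bin and CIM sharpens the profile", {
  cfg <- twoChromConfig(n_rils = 150, n_variants = 500, seed = 9)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  lm_ <- buildLinkageMap(bm$binmap)
  ph <- st$phenotypes[st$phenotypes$trait == "AC" &
                        st$phenotypes$environment == "18CD", ]
  y <- stats::setNames(ph$value, ph$sample)
  prof <- genomeScan(y, lm_, bm$binmap, max_cofactors = 0)
  expect_equal(nrow(prof), nrow(bm$binmap))   # one row per bin
  peak <- prof[which.max(prof$LOD), ]
  expect_equal(peak$chrom, "Chr1")
  expect_lt(abs(peak$pos_bp - 1.5e6), 3e5)
  # CIM path runs and keeps the same peak chromosome
  prof2 <- genomeScan(y, lm_, bm$binmap, max_cofactors = 3)
  expect_equal(prof2$chrom[which.max(prof2$LOD)], "Chr1")
})

test_that("permutation thresholds are deterministic and hit quantile edges", {
  cfg <- twoChromConfig(n_rils = 80, n_variants = 400, seed = 14,
                        causal = NULL)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  lm_ <- buildLinkageMap(bm$binmap)
  set.seed(50)
  y <- stats::setNames(rbinom(ncol(bm$binmap), 1, 0.5),
                       colnames(genoCalls(bm$binmap)))
  t1 <- permutationThreshold(y, lm_, bm$binmap, n_perm = 150, seed = 4)
  t2 <- permutationThreshold(y, lm_, bm$binmap, n_perm = 150, seed = 4)
  expect_identical(t1, t2)
  tmin <- permutationThreshold(y, lm_, bm$binmap, n_perm = 150, alpha = 1,
                               seed = 4)
  expect_lte(tmin, t1)
  expect_error(permutationThreshold(y, lm_, bm$binmap, n_perm = 50), ">= 100")
})

test_that("QTL calling respects thresholds and interval conventions", {
  cfg <- twoChromConfig(n_rils = 150, n_variants = 500, seed = 9)
  st <- simulateStudy(cfg)
  bm <- binMarkers(st$genotypes)
  lm_ <- buildLinkageMap(bm$binmap)
  ph <- st$phenotypes[st$phenotypes$trait == "AC" &
                        st$phenotypes$environment == "18CD", ]
  y <- stats::setNames(ph$value, ph$sample)
  prof <- genomeScan(y, lm_, bm$binmap, max_cofactors = 0)
  q <- callQTL(prof, bm$binmap)
  expect_gt(nrow(q), 0)
  expect_true(all(q$LOD > 3))
  expect_true(all(q$r2 > 5))
  expect_equal(q$interval_bp, q$interval_end - q$interval_start + 1)
  # the causal position falls inside the called region span
  qc <- q[q$chrom == "Chr1", ]
  expect_true(any(qc$region_start <= 1.5e6 & qc$region_end >= 1.5e6))
  # a flat profile yields no QTL
  flat <- prof; flat$LOD <- 0.5
  expect_equal(nrow(callQTL(flat, bm$binmap)), 0)
})

test_that("monogenic QTL power: causal locus inside the called QTL region", {
  hits <- vapply(1:10, function(seed) {
    cfg <- twoChromConfig(n_rils = 200, n_variants = 500, seed = 100 + seed,
                          causal = data.frame(chrom = "Chr1", pos = 1.5e6,
                                              trait = "AC",
                                              penetrance = 0.95))
    st <- simulateStudy(cfg)
    bm <- binMarkers(st$genotypes)
    lm_ <- buildLinkageMap(bm$binmap)
    ph <- st$phenotypes[st$phenotypes$trait == "AC" &
                          st$phenotypes$environment == "18CD", ]
    y <- stats::setNames(ph$value, ph$sample)
    prof <- genomeScan(y, lm_, bm$binmap, max_cofactors = 0)
    q <- callQTL(prof, bm$binmap)
    # the strongest peak must sit on the causal chromosome and its
    # super-threshold region must cover the causal position
    top <- q[which.max(q$LOD + q$r2 * 1e-6), ]
    nrow(q) > 0 && top$chrom == "Chr1" &&
      top$region_start <= 1.5e6 && top$region_end >= 1.5e6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
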