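#' Run the whole mapping pipeline on a simulated study
#'
#' Chains every stage end to end: simulate a RIL study from the
#' configuration, filter parent-informative and population-quality
#' markers, screen samples by heterozygosity, build the bin map and the
#' genetic map, scan each trait for QTL (with an optional permutation
#' threshold), fine-map with inconsistent rate analysis, and — when a
#' gene-annotation fixture is supplied — nominate candidate genes. All
#' stage artifacts are written under \code{outdir} and a summary (counts
#' per stage) is returned and written as JSON. Fully deterministic under
#' the configuration seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir output directory (created if needed).
#' @param n_perm permutations for the LOD threshold; 0 uses the fixed
#'   \code{lod_min} only (default 0 for speed).
#' @param lod_min,r2_min QTL calling thresholds.
#' @param window_size,cutoff,min_run bin-calling parameters.
#' @param ira_window,ira_step,ira_cutoff IRA parameters.
#' @param annotation optional list(genes, genome, variants, descriptions)
#'   as produced by \code{\link{simulateGeneFixture}} for the annotation
#'   stage.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config, outdir, n_perm = 0L, lod_min = 3,
                        r2_min = 5, window_size = 15L, cutoff = 0.7,
                        min_run = 3L, ira_window = 50000,
                        ira_step = 10000, ira_cutoff = 0.10,
                        annotation = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulateStudy(config)
  writeGenotypeVCF(study$genotypes, file.path(outdir, "genotypes.vcf"))
  if (!is.null(study$phenotypes))
    writePhenotypes(study$phenotypes, file.path(outdir, "phenotypes.tsv"))

  pi <- filterParentInformative(rowRanges(study$genotypes))
  geno <- study$genotypes[pi$keep, ]
  fp <- filterPopulation(geno)
  sh <- sampleHeterozygosity(fp$genotypes)
  geno <- sh$genotypes

  bm <- binMarkers(geno, window_size = window_size, cutoff = cutoff,
                   min_run = min_run)
  writeBinMap(bm$binmap, file.path(outdir, "binmap.tsv"))
  lm_ <- buildLinkageMap(bm$binmap)
  writeLinkageMap(lm_, file.path(outdir, "genetic_map.tsv"))

  traits <- unique(config@causal_loci$trait)
  qtl_all <- list(); ira_all <- list()
  for (tr in traits) {
    ph <- study$phenotypes[study$phenotypes$trait == tr, ]
    yv <- tapply(ph$value, ph$sample, mean)
    y <- stats::setNames(as.numeric(yv >= 0.5), names(yv))
    prof <- genomeScan(y, lm_, bm$binmap, max_cofactors = 0L)
    thr <- if (n_perm > 0L)
      permutationThreshold(y, lm_, bm$binmap, n_perm = n_perm,
                           seed = config@seed + 10L) else lod_min
    q <- callQTL(prof, bm$binmap, lod_min = max(lod_min, thr),
                 r2_min = r2_min)
    if (nrow(q)) q <- cbind(trait = tr, q)
    qtl_all[[tr]] <- q
    utils::write.table(prof, file.path(outdir, paste0("scan_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ira <- iraScan(geno, study$phenotypes, tr, window = ira_window,
                   step = ira_step, cutoff = ira_cutoff)
    ira_all[[tr]] <- ira
    utils::write.table(ira$windows,
                       file.path(outdir, paste0("ira_windows_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(ira$regions))
      writeRegionsBED(ira$regions,
                      file.path(outdir, paste0("ira_regions_", tr, ".bed")))
  }
  qtl <- do.call(rbind, qtl_all[vapply(qtl_all, nrow, 1L) > 0])
  if (!is.null(qtl))
    utils::write.table(qtl, file.path(outdir, "qtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  n_candidates <- NA_integer_
  if (!is.null(annotation)) {
    regions <- do.call(c, unname(lapply(ira_all, `[[`, "regions")))
    cg <- candidateGenes(regions, annotation$variants, annotation$genes,
                         annotation$genome, annotation$descriptions)
    utils::write.table(cg$candidates, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_candidates <- length(unique(cg$candidates$gene))
  }

  summary <- list(
    seed = config@seed,
    n_sites_catalog = length(study$catalog),
    n_sites_informative = pi$report$n_retained,
    n_sites_retained = fp$report$n_retained,
    n_samples_input = sh$report$n_input,
    n_samples_dropped = sh$report$n_removed,
    n_bins = nrow(bm$binmap),
    map_length_cm = totalMapLength(lm_),
    mean_bin_interval_cm = meanBinInterval(lm_),
    n_qtl = if (is.null(qtl)) 0L else nrow(qtl),
    n_ira_regions = sum(vapply(ira_all, function(x) length(x$regions), 1L)),
    n_candidate_genes = n_candidates)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
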