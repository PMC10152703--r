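## End-to-end orchestration: inputs -> tiered call set, QC metrics, LD tables,
## disruption tables, summary report. All module thresholds default to the
## values documented on their home functions.

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention used for reporting headline fractions (e.g. 229/371 -> 62).
#'
#' @param numerator,denominator non-negative integers, `denominator > 0`,
#'   `numerator <= denominator`.
#' @param decimals digits after the point.
#' @return percentage as a number.
#' @export
fractionPercent <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  floor(x * f + 0.5 + 1e-9) / f
}

#' Per-site QC plot table
#'
#' The data behind a per-site genotype/depth QC plot: one row per sample with
#' genotype and the type-appropriate fold-coverage value (DHFFC for
#' deletions, DHBFC otherwise); missing-genotype samples are flagged, not
#' dropped. Group means and SDs are attached as the `"groups"` attribute.
#'
#' @param cohort an [SVCohort].
#' @param site site id or row index.
#' @return data.frame: `sample`, `gt` (0/1/2/NA), `fold`, `missing`;
#'   attribute `groups` holds per-genotype n/mean/sd.
#' @export
qcPlotTable <- function(cohort, site) {
  i <- if (is.character(site)) match(site, siteIDs(cohort)) else site
  if (is.na(i)) stop("unknown site: ", site)
  gt <- genotypes(cohort)[i, ]
  fold <- if (svType(cohort)[i] == "DEL") dhffc(cohort)[i, ] else
    dhbfc(cohort)[i, ]
  tab <- data.frame(sample = colnames(cohort), gt = gt, fold = fold,
                    missing = is.na(gt))
  rownames(tab) <- NULL
  grp <- do.call(rbind, lapply(0:2, function(g) {
    v <- fold[!is.na(gt) & gt == g]
    data.frame(gt = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  attr(tab, "groups") <- grp
  tab
}

#' Run the full curation pipeline
#'
#' Reads the inputs, fails fast on sample-id mismatches, runs the filter
#' cascade, classifies the clean set into tiers, computes trio and population
#' QC metrics, the LD tagging analyses and the gene-disruption tables, and
#' writes every stage's output (TSV + tiered VCF + a JSON run manifest) to
#' `out_dir`. Deterministic for fixed inputs and seed.
#'
#' @param vcf,ped,snps,genes input paths (SV VCF, pedigree, SNP dosage TSV,
#'   GFF3/BED12 gene models). `snps` and `genes` may be `NULL` to skip those
#'   stages. Alternatively pass pre-built objects of the matching classes.
#' @param out_dir output directory.
#' @param min_size,min_reciprocal_overlap,r2_threshold,ld_window,
#'   kde_bandwidth,min_peak_separation,n_resample_draws module thresholds
#'   (defaults are the documented per-module defaults).
#' @param seed integer seed used for every stochastic step (resampling).
#' @return (invisibly) list with `cohort`, `filter` (cascade result),
#'   `tiers`, `mendelian`, `af`, `sfs`, `breakpoints`, `per_sample`,
#'   `ld` (pairs/tagging/decay), `disruption`, `summary`.
#' @export
runPipeline <- function(vcf, ped, snps = NULL, genes = NULL,
                        out_dir = tempfile("svcurate_run"),
                        min_size = 50L, min_reciprocal_overlap = 0.95,
                        r2_threshold = 0.8, ld_window = 100000L,
                        kde_bandwidth = NULL, min_peak_separation = 0.2,
                        n_resample_draws = 1000L, seed = 1L) {
  cohort <- if (is(vcf, "SVCohort")) vcf else readSVVcf(vcf)
  trios <- if (is.data.frame(ped)) ped else readPedigree(ped)
  absent <- setdiff(unique(unlist(trios[c("offspring", "father", "mother")])),
                    colnames(cohort))
  if (length(absent))
    stop("sample id(s) in pedigree but not in VCF: ",
         paste(absent, collapse = ", "))
  snps <- if (is.null(snps) || is(snps, "GenotypeMatrix")) snps else
    readGenotypeMatrix(snps)
  genes <- if (is.null(genes) || is.list(genes)) genes else
    readGeneModels(genes)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_counts <- list(input = nrow(cohort))

  filt <- runFilterCascade(cohort, min_size = min_size,
                           min_reciprocal_overlap = min_reciprocal_overlap)
  clean <- filt$clean
  log_counts$clean <- nrow(clean)
  tiers <- classifyCleanCallset(clean, bandwidth = kde_bandwidth,
                                min_peak_separation = min_peak_separation)
  rowData(clean)$tier <- tiers$tier
  log_counts$tiers <- table(tiers$tier)

  mend <- cbind(
    mendelianErrorFraction(clean, trios, "all_trios"),
    effective_fraction =
      mendelianErrorFraction(clean, trios, "effective_trios")$fraction)
  af <- alleleFrequencies(clean)
  sfs <- siteFrequencySpectrum(clean)
  bres <- breakpointResolutionSummary(clean, tiers)
  psc <- perSampleCounts(clean, tiers,
                         tier_filter = c("STRINGENT", "LENIENT", "MCNV"))

  ld <- NULL
  if (!is.null(snps)) {
    stringent <- clean[tiers$tier == "STRINGENT", ]
    pairs <- cnvSnpPairs(stringent, snps, window = ld_window,
                         exclude_mcnv = TRUE, tiers = tiers)
    tagging <- taggingFraction(pairs, threshold = r2_threshold)
    decay <- ldDecayProfile(pairs)
    ld <- list(pairs = pairs, tagging = tagging, decay = decay)
    write.table(pairs, file.path(out_dir, "ld_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(decay, file.path(out_dir, "ld_decay.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  disruption <- NULL
  if (!is.null(genes)) {
    calls <- classifyGeneOverlap(clean, genes)
    disruption <- list(calls = calls,
                       burden = perSampleBurden(calls, clean),
                       genes = affectedGeneSummary(calls))
    write.table(calls, file.path(out_dir, "disruption_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeSVVcf(clean, file.path(out_dir, "clean_tiered.vcf"), labels = tiers)
  write.table(filt$ledger, file.path(out_dir, "filter_ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(filt$summary, file.path(out_dir, "filter_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tiers, file.path(out_dir, "tiers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(mend, file.path(out_dir, "mendelian.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sfs, file.path(out_dir, "sfs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(psc$per_sample, file.path(out_dir, "per_sample_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "svcurate",
    version = as.character(utils::packageVersion("svcurate")),
    seed = seed,
    thresholds = list(min_size = min_size,
                      min_reciprocal_overlap = min_reciprocal_overlap,
                      r2_threshold = r2_threshold, ld_window = ld_window,
                      min_peak_separation = min_peak_separation),
    counts = list(input = log_counts$input, clean = log_counts$clean,
                  tiers = as.list(log_counts$tiers)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_manifest.json"))

  invisible(list(cohort = cohort, filter = filt, clean = clean,
                 tiers = tiers, mendelian = mend, af = af, sfs = sfs,
                 breakpoints = bres, per_sample = psc, ld = ld,
                 disruption = disruption, out_dir = out_dir,
                 summary = manifest$counts))
}
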