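## Trio-based and population-level quality metrics.

#' Classify one trio genotype triple
#'
#' A trio shows a Mendelian inheritance error when the offspring genotype
#' cannot be assembled from one allele of each parent. Any missing genotype
#' makes the trio uninformative at that site.
#'
#' @param gt_father,gt_mother,gt_offspring dosages (0/1/2, `NA` = missing);
#'   vectors are processed elementwise.
#' @return character vector: `"error"`, `"consistent"` or `"uninformative"`.
#' @export
trioMendelianError <- function(gt_father, gt_mother, gt_offspring) {
  alleles <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  out <- character(length(gt_father))
  for (i in seq_along(out)) {
    f <- gt_father[i]; m <- gt_mother[i]; o <- gt_offspring[i]
    if (is.na(f) || is.na(m) || is.na(o)) { out[i] <- "uninformative"; next }
    possible <- outer(alleles[[f + 1L]], alleles[[m + 1L]], `+`)
    out[i] <- if (o %in% possible) "consistent" else "error"
  }
  out
}

#' Per-site Mendelian error fraction
#'
#' In `all_trios` mode the denominator is the fixed trio count (trios with a
#' missing member stay in the denominator but cannot contribute errors). In
#' `effective_trios` mode the denominator is the number of fully genotyped
#' trios in which at least one member carries at least one alternative allele;
#' the fraction is `NA` when that denominator is 0.
#'
#' @param cohort an [SVCohort] (or a dosage matrix sites x samples).
#' @param trios data.frame from [readPedigree].
#' @param denominator `"all_trios"` or `"effective_trios"`.
#' @return data.frame: `site_id`, `n_errors`, `n_trios`, `fraction`.
#' @export
mendelianErrorFraction <- function(cohort, trios,
                                   denominator = c("all_trios",
                                                   "effective_trios")) {
  denominator <- match.arg(denominator)
  gt <- if (is.matrix(cohort)) cohort else genotypes(cohort)
  if (nrow(trios) < 1L) stop("at least one trio is required")
  validatePedigree(trios, colnames(gt))
  fa <- gt[, trios$father, drop = FALSE]
  mo <- gt[, trios$mother, drop = FALSE]
  of <- gt[, trios$offspring, drop = FALSE]
  complete <- !(is.na(fa) | is.na(mo) | is.na(of))
  ## error iff offspring has an allele with no parental source:
  ## impossible combinations of biallelic transmission
  err <- complete & ((fa == 0L & mo == 0L & of > 0L) |
                     (fa == 2L & mo == 2L & of < 2L) |
                     (fa == 0L & mo == 2L & of != 1L) |
                     (fa == 2L & mo == 0L & of != 1L) |
                     (fa == 0L & mo == 1L & of == 2L) |
                     (fa == 1L & mo == 0L & of == 2L) |
                     (fa == 2L & mo == 1L & of == 0L) |
                     (fa == 1L & mo == 2L & of == 0L))
  n_err <- rowSums(err)
  denom <- if (denominator == "all_trios") {
    rep(nrow(trios), nrow(gt))
  } else {
    rowSums(complete & (fa > 0L | mo > 0L | of > 0L))
  }
  frac <- ifelse(denom > 0, n_err / denom, NA_real_)
  data.frame(site_id = rownames(gt), n_errors = n_err, n_trios = denom,
             fraction = frac)
}

#' Per-site allele frequencies
#'
#' AF is the alternative allele count over twice the number of non-missing
#' calls; sites with a call rate under `flag_call_rate` are flagged.
#'
#' @param cohort an [SVCohort].
#' @param flag_call_rate call-rate threshold for the `low_call_rate` flag.
#' @return data.frame: `site_id`, `allele_count`, `n_called`, `af`, `maf`,
#'   `low_call_rate`.
#' @export
alleleFrequencies <- function(cohort, flag_call_rate = 0.5) {
  gt <- genotypes(cohort)
  n_called <- rowSums(!is.na(gt))
  ac <- rowSums(gt, na.rm = TRUE)
  af <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  data.frame(site_id = siteIDs(cohort), allele_count = ac,
             n_called = n_called, af = af, maf = pmin(af, 1 - af),
             low_call_rate = n_called < flag_call_rate * ncol(gt))
}

#' Site frequency spectrum
#'
#' Histogram of per-site allele frequencies (or MAFs); the counts sum to the
#' number of input sites with a defined frequency. Per-svtype spectra are
#' returned alongside the total.
#'
#' @param cohort an [SVCohort].
#' @param bins bin edges over [0, 1] (or [0, 0.5] for MAF).
#' @param use_maf bin minor-allele instead of alternative-allele frequency.
#' @return data.frame: `bin_lo`, `bin_hi`, `svtype` (including `"ALL"`),
#'   `count`.
#' @export
siteFrequencySpectrum <- function(cohort, bins = seq(0, 1, by = 0.05),
                                  use_maf = FALSE) {
  af <- alleleFrequencies(cohort)
  x <- if (use_maf) af$maf else af$af
  types <- svType(cohort)
  one <- function(vals, label) {
    h <- hist(vals[!is.na(vals)], breaks = bins, plot = FALSE,
              include.lowest = TRUE, right = TRUE)
    data.frame(bin_lo = head(bins, -1), bin_hi = bins[-1], svtype = label,
               count = h$counts)
  }
  out <- rbind(one(x, "ALL"),
               do.call(rbind, lapply(unique(types), function(tp)
                 one(x[types == tp], tp))))
  rownames(out) <- NULL
  out
}

#' Breakpoint resolution summary
#'
#' A site is single-base resolved when both breakpoint confidence intervals
#' are absent or zero-width.
#'
#' @param cohort an [SVCohort].
#' @param tiers optional tier labels (data.frame `site_id`, `tier`) for a
#'   per-tier breakdown.
#' @return list with `fraction`, `n_resolved`, `n_total` and (when tiers are
#'   supplied) `by_tier`.
#' @export
breakpointResolutionSummary <- function(cohort, tiers = NULL) {
  rd <- rowData(cohort)
  zero <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & a == 0 & b == 0)
  resolved <- zero(rd$cipos1, rd$cipos2) & zero(rd$ciend1, rd$ciend2)
  out <- list(fraction = mean(resolved), n_resolved = sum(resolved),
              n_total = length(resolved))
  if (!is.null(tiers)) {
    m <- setNames(tiers$tier, tiers$site_id)[siteIDs(cohort)]
    out$by_tier <- aggregate(resolved, by = list(tier = m), FUN = mean)
    names(out$by_tier)[2] <- "fraction"
  }
  out
}

#' Per-sample SV carriage counts
#'
#' A sample carries a site when its genotype is 0/1 or 1/1. Returns counts per
#' sample and svtype, plus cohort medians.
#'
#' @param cohort an [SVCohort].
#' @param tiers optional tier labels; with `tier_filter`, restricts counting
#'   to sites of those tiers.
#' @param tier_filter character vector of tiers to keep.
#' @return list with `per_sample` (data.frame: sample, svtype, count) and
#'   `median` (named vector per svtype plus `ALL`).
#' @export
perSampleCounts <- function(cohort, tiers = NULL, tier_filter = NULL) {
  if (!is.null(tiers) && !is.null(tier_filter)) {
    keep <- siteIDs(cohort) %in% tiers$site_id[tiers$tier %in% tier_filter]
    cohort <- cohort[keep, ]
  }
  gt <- genotypes(cohort)
  carried <- !is.na(gt) & gt > 0L
  types <- svType(cohort)
  per <- do.call(rbind, lapply(unique(types), function(tp) {
    data.frame(sample = colnames(gt), svtype = tp,
               count = colSums(carried[types == tp, , drop = FALSE]))
  }))
  all_counts <- colSums(carried)
  per <- rbind(per, data.frame(sample = colnames(gt), svtype = "ALL",
                               count = all_counts))
  rownames(per) <- NULL
  med <- vapply(split(per$count, per$svtype), median, numeric(1))
  list(per_sample = per, median = med)
}
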