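## Partition the clean call set into stringent / lenient / mCNV tiers.
##
## A stringent site is one whose read-depth fold-coverage corresponds
## unambiguously to the reads-based genotypes: the per-genotype depth
## distributions are fully ordered and non-overlapping. Multi-allelic CNVs
## betray themselves by more than three modes in the cohort-wide depth
## distribution.

#' Stringent criteria for deletions
#'
#' Passes when the DHFFC distributions of the genotype groups are fully
#' separated in copy-number order: the highest 0/1 value is below the lowest
#' 0/0 value, the highest 1/1 value is below the lowest 0/1 value (when both
#' groups exist), and the lowest 0/1 value is not 0. Clauses over empty
#' groups pass vacuously. With `strict_printed = TRUE` the second clause
#' instead requires the highest 0/0 value to be below the lowest 0/1 value —
#' the literal printed form, which contradicts the first clause whenever both
#' groups are non-empty and is therefore not the default (see the vignette).
#'
#' @param stats `gt_group_stats` on DHFFC.
#' @param strict_printed use the literal (mutually contradictory) clause pair.
#' @return list with `pass` and `failing` criterion id (`"a"`, `"b"`, `"c"`
#'   or `NA`).
#' @export
stringentDeletionTest <- function(stats, strict_printed = FALSE) {
  fail <- function(id) list(pass = FALSE, failing = id)
  if (stats$n["g1"] > 0 && stats$n["g0"] > 0 &&
      !(stats$max["g1"] < stats$min["g0"])) return(fail("a"))
  if (strict_printed) {
    if (stats$n["g0"] > 0 && stats$n["g1"] > 0 &&
        !(stats$max["g0"] < stats$min["g1"])) return(fail("b"))
  } else {
    if (stats$n["g2"] > 0 && stats$n["g1"] > 0 &&
        !(stats$max["g2"] < stats$min["g1"])) return(fail("b"))
  }
  if (stats$n["g1"] > 0 && stats$min["g1"] == 0) return(fail("c"))
  list(pass = TRUE, failing = NA_character_)
}

#' Stringent criteria for duplications
#'
#' Passes when the DHBFC distributions are fully separated in ascending
#' copy-number order: the lowest 0/1 value is above the highest 0/0 value,
#' the lowest 1/1 value is above the highest 0/1 value, and neither carrier
#' minimum is 0. Clauses over empty groups pass vacuously.
#'
#' @param stats `gt_group_stats` on DHBFC.
#' @return list with `pass` and `failing` (`"a"`, `"b"`, `"c"`, `"d"` or `NA`).
#' @export
stringentDuplicationTest <- function(stats) {
  fail <- function(id) list(pass = FALSE, failing = id)
  if (stats$n["g1"] > 0 && stats$n["g0"] > 0 &&
      !(stats$min["g1"] > stats$max["g0"])) return(fail("a"))
  if (stats$n["g2"] > 0 && stats$n["g1"] > 0 &&
      !(stats$min["g2"] > stats$max["g1"])) return(fail("b"))
  if (stats$n["g1"] > 0 && stats$min["g1"] == 0) return(fail("c"))
  if (stats$n["g2"] > 0 && stats$min["g2"] == 0) return(fail("d"))
  list(pass = TRUE, failing = NA_character_)
}

#' Count modes of a fold-coverage distribution
#'
#' Kernel-density surrogate for the by-eye screening of QC plots: modes are
#' local maxima of a Gaussian KDE over the values, with maxima closer than
#' `min_peak_separation` merged into one and maxima whose density is below
#' `min_peak_fraction` of the tallest peak ignored (a lone outlier sample is
#' not a mode). The default bandwidth is Silverman's rule-of-thumb scaled by
#' 0.5 and capped at `min_peak_separation / 2`: the rule-of-thumb assumes
#' unimodality and over-smooths strongly multimodal depth distributions, and
#' a kernel wider than half the separation cannot resolve the modes being
#' screened for.
#'
#' @param fold_values numeric vector of per-sample fold-coverage values.
#' @param bandwidth KDE bandwidth (fold units);
#'   default `min(0.5 * bw.nrd0, min_peak_separation / 2)`.
#' @param min_peak_separation minimum distance between distinct modes.
#' @param min_peak_fraction minimum peak density relative to the tallest peak.
#' @return integer mode count, or `NA` when fewer than 10 values are
#'   available (multimodality undetermined).
#' @export
detectMultimodality <- function(fold_values, bandwidth = NULL,
                                min_peak_separation = 0.2,
                                min_peak_fraction = 0.05) {
  v <- fold_values[!is.na(fold_values)]
  if (length(v) < 10L) return(NA_integer_)
  if (is.null(bandwidth)) {
    bw0 <- bw.nrd0(v)
    if (!is.finite(bw0) || bw0 <= 0) return(1L)  # degenerate: all values equal
    bandwidth <- min(0.5 * bw0, min_peak_separation / 2)
  }
  d <- density(v, bw = bandwidth, n = 512L)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1L
  ## flat-topped maxima (plateaus) are rare on a 512-point grid but possible
  if (!length(peak)) peak <- which.max(y)
  peak <- peak[y[peak] >= min_peak_fraction * max(y[peak])]
  locs <- sort(d$x[peak])
  n_modes <- 1L
  for (k in seq_along(locs)[-1]) {
    if (locs[k] - locs[k - 1L] >= min_peak_separation)
      n_modes <- n_modes + 1L
    else
      locs[k] <- locs[k - 1L]  # merged: keep comparing against the cluster
  }
  n_modes
}

#' Classify the clean call set into stringent / lenient / mCNV tiers
#'
#' Duplications whose cohort-wide DHBFC distribution has more than three
#' modes are re-labelled mCNV (more than two structural alleles segregating);
#' remaining sites are STRINGENT when the type-appropriate stringent test
#' passes and LENIENT otherwise. The output partitions the input.
#'
#' @param clean a depth-filtered [SVCohort] (from [runFilterCascade]).
#' @param mcnv_on_deletions also screen deletions for multimodality
#'   (off by default: multi-allelic loci present as duplications).
#' @param bandwidth,min_peak_separation passed to [detectMultimodality].
#' @param strict_printed passed to [stringentDeletionTest].
#' @return data.frame with `site_id`, `tier` (STRINGENT/LENIENT/MCNV),
#'   `failing_criterion`, `n_modes`.
#' @export
classifyCleanCallset <- function(clean, mcnv_on_deletions = FALSE,
                                 bandwidth = NULL, min_peak_separation = 0.2,
                                 strict_printed = FALSE) {
  n <- nrow(clean)
  gt <- genotypes(clean); ff <- dhffc(clean); bf <- dhbfc(clean)
  types <- svType(clean)
  tier <- character(n); failing <- rep(NA_character_, n)
  n_modes <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    screen <- types[i] == "DUP" || (mcnv_on_deletions && types[i] == "DEL")
    if (screen) {
      nm <- detectMultimodality(bf[i, ], bandwidth, min_peak_separation)
      n_modes[i] <- nm
      if (!is.na(nm) && nm > 3L) { tier[i] <- "MCNV"; next }
    }
    vals <- if (types[i] == "DEL") ff[i, ] else bf[i, ]
    st <- groupStatsFromValues(gt[i, ], vals)
    res <- if (types[i] == "DEL") {
      stringentDeletionTest(st, strict_printed = strict_printed)
    } else stringentDuplicationTest(st)
    tier[i] <- if (res$pass) "STRINGENT" else "LENIENT"
    failing[i] <- res$failing
  }
  data.frame(site_id = siteIDs(clean), tier = tier,
             failing_criterion = failing, n_modes = n_modes)
}
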