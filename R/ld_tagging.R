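## CNV-SNP linkage disequilibrium and tagging.
##
## r2 is the squared Pearson correlation of 0/1/2 dosages over
## pairwise-complete samples (composite, unphased measure — the default
## behaviour of standard LD tools on unphased genotypes). Haplotype-EM r2 is
## deliberately out of scope.

#' Genotypes to dosage
#' @param gt vector of biallelic dosages or genotype strings
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`).
#' @return integer dosage vector (0/1/2/NA), same length.
#' @export
dosageFromGenotypes <- function(gt) {
  if (is.numeric(gt)) return(as.integer(gt))
  out <- GT_TO_DOSAGE[as.character(gt)]
  unname(out)
}

#' Composite r2 between two dosage vectors
#'
#' Squared Pearson correlation over samples where both dosages are
#' non-missing. Undefined (NA) when fewer than two complete pairs remain or
#' either locus is monomorphic among them; such pairs are excluded from all
#' summaries.
#'
#' @param dosage_a,dosage_b integer dosage vectors (0/1/2/NA).
#' @return squared correlation in [0, 1], or `NA`.
#' @export
pairwiseR2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Haplotype-counting r2 (phased oracle)
#'
#' Classical two-locus r2 from phased haplotype counts:
#' `D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`. Used as the
#' independent cross-check of the composite measure on phased synthetic
#' founders.
#'
#' @param hap_a,hap_b binary haplotype vectors of equal length.
#' @return r2 in [0, 1], or `NA` when a locus is monomorphic.
#' @export
haplotypeR2 <- function(hap_a, hap_b) {
  pA <- mean(hap_a); pB <- mean(hap_b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- mean(hap_a * hap_b) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Form CNV-SNP pairs within an LD window
#'
#' Pairs each CNV with every SNP lying strictly outside the CNV interval and
#' within `window` bp (inclusive) of either breakpoint. The pair distance is
#' the distance to the nearest breakpoint.
#'
#' @param cnvs an [SVCohort] (CNV loci, e.g. the stringent call set).
#' @param snps a [GenotypeMatrix] of SNP loci.
#' @param window window size in bp (inclusive boundary).
#' @param exclude_mcnv drop CNVs labelled MCNV in `tiers` (their biallelic
#'   genotypes are unreliable); a flag, so the mCNV analysis stays possible.
#' @param tiers optional tier labels for `exclude_mcnv`.
#' @return data.frame of LD pairs: `cnv_id`, `snp_id`, `svtype`, `distance`,
#'   `maf_cnv`, `maf_snp`, `r2` (NA r2 rows are retained here, excluded by
#'   downstream summaries).
#' @export
cnvSnpPairs <- function(cnvs, snps, window = 100000L, exclude_mcnv = TRUE,
                        tiers = NULL) {
  if (exclude_mcnv && !is.null(tiers)) {
    drop <- tiers$site_id[tiers$tier == "MCNV"]
    cnvs <- cnvs[!siteIDs(cnvs) %in% drop, ]
  }
  sl <- loci(snps)
  snp_d <- dosages(snps)
  gt <- genotypes(cnvs)
  gr <- rowRanges(cnvs)
  maf_of <- function(d) {
    p <- mean(d, na.rm = TRUE) / 2
    min(p, 1 - p)
  }
  res <- vector("list", nrow(cnvs))
  for (i in seq_len(nrow(cnvs))) {
    chrom <- as.character(seqnames(gr)[i])
    p <- start(gr)[i]; e <- end(gr)[i]
    cand <- which(sl$chrom == chrom & !sl$is_cnv &
                    (sl$pos < p | sl$pos > e) &
                    (abs(sl$pos - p) <= window | abs(sl$pos - e) <= window))
    if (!length(cand)) next
    dist <- pmin(abs(sl$pos[cand] - p), abs(sl$pos[cand] - e))
    r2 <- vapply(cand, function(j) pairwiseR2(gt[i, ], snp_d[j, ]),
                 numeric(1))
    res[[i]] <- data.frame(
      cnv_id = siteIDs(cnvs)[i], snp_id = sl$locus_id[cand],
      svtype = svType(cnvs)[i], distance = dist,
      maf_cnv = maf_of(gt[i, ]),
      maf_snp = vapply(cand, function(j) maf_of(snp_d[j, ]), numeric(1)),
      r2 = r2)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cnv_id = character(), snp_id = character(),
                      svtype = character(), distance = integer(),
                      maf_cnv = numeric(), maf_snp = numeric(),
                      r2 = numeric())
  rownames(out) <- NULL
  out
}

#' Fraction of CNVs tagged by at least one SNP
#'
#' A CNV is tagged when at least one of its pairs has `r2 > threshold`
#' (strict). Fractions are reported over CNVs that have at least one pair
#' with a defined r2; CNVs with no eligible SNP are counted separately.
#'
#' @param pairs data.frame from [cnvSnpPairs].
#' @param threshold tagging threshold (strict inequality).
#' @param maf_common MAF cut separating common from rare CNVs.
#' @return list with `overall` (fraction), `by_type` (data.frame: svtype,
#'   maf_class, n_cnv, n_tagged, fraction) and `n_no_pair` CNV count without
#'   eligible pairs.
#' @export
taggingFraction <- function(pairs, threshold = 0.8, maf_common = 0.05) {
  usable <- pairs[!is.na(pairs$r2), , drop = FALSE]
  n_no_pair <- length(setdiff(unique(pairs$cnv_id), unique(usable$cnv_id)))
  if (!nrow(usable))
    return(list(overall = NA_real_, by_type = data.frame(),
                n_no_pair = n_no_pair))
  per_cnv <- aggregate(r2 ~ cnv_id + svtype + maf_cnv, data = usable,
                       FUN = max)
  per_cnv$tagged <- per_cnv$r2 > threshold
  per_cnv$maf_class <- ifelse(per_cnv$maf_cnv >= maf_common,
                              "common", "rare")
  by_type <- aggregate(tagged ~ svtype + maf_class, data = per_cnv,
                       FUN = function(x) c(n = length(x), k = sum(x)))
  by_type <- data.frame(svtype = by_type$svtype,
                        maf_class = by_type$maf_class,
                        n_cnv = by_type$tagged[, "n"],
                        n_tagged = by_type$tagged[, "k"])
  by_type$fraction <- by_type$n_tagged / by_type$n_cnv
  list(overall = mean(per_cnv$tagged), by_type = by_type,
       n_no_pair = n_no_pair)
}

#' LD decay profile over distance bins
#'
#' Mean r2 per inter-marker distance bin, stratified by the MAF class of the
#' CNV (common >= `maf_common` vs rare). Bin means over zero pairs are
#' reported as `NA`.
#'
#' @param pairs data.frame with `distance`, `r2` and (optionally) `maf_cnv`.
#' @param bins distance bin edges in bp.
#' @param maf_common MAF cut for stratification.
#' @return data.frame: `bin_lo`, `bin_hi`, `maf_class`, `mean_r2`, `count`.
#' @export
ldDecayProfile <- function(pairs, bins = seq(0, 100000, by = 10000),
                           maf_common = 0.05) {
  usable <- pairs[!is.na(pairs$r2), , drop = FALSE]
  maf_class <- if ("maf_cnv" %in% names(usable)) {
    ifelse(usable$maf_cnv >= maf_common, "common", "rare")
  } else rep("all", nrow(usable))
  bin <- cut(usable$distance, breaks = bins, include.lowest = TRUE)
  grid <- expand.grid(bin = levels(bin),
                      maf_class = unique(c(maf_class, character())),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    sel <- !is.na(bin) & bin == grid$bin[k] & maf_class == grid$maf_class[k]
    data.frame(bin_lo = bins[match(grid$bin[k], levels(bin))],
               bin_hi = bins[match(grid$bin[k], levels(bin)) + 1L],
               maf_class = grid$maf_class[k],
               mean_r2 = if (any(sel)) mean(usable$r2[sel]) else NA_real_,
               count = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Matched SNP-SNP resampling
#'
#' Repeatedly draws subsets of SNP-SNP pairs of the same size as a CNV-SNP
#' pair set (without replacement), computes the per-bin mean r2 of each draw,
#' and reports the mean and standard deviation across draws — the fair-
#' comparison device for pair sets of very different sizes.
#'
#' @param snp_snp_pairs data.frame with `distance` and `r2`.
#' @param n_match subset size (the number of CNV-SNP pairs to match).
#' @param n_draws number of resampling draws.
#' @param bins distance bin edges.
#' @param seed seed making the draws reproducible.
#' @return data.frame: `bin_lo`, `bin_hi`, `mean_r2` (mean of per-draw bin
#'   means), `sd_r2`, `mean_count`.
#' @export
matchedSnpResampling <- function(snp_snp_pairs, n_match, n_draws = 1000L,
                                 bins = seq(0, 100000, by = 10000),
                                 seed = NULL) {
  usable <- snp_snp_pairs[!is.na(snp_snp_pairs$r2), , drop = FALSE]
  if (n_match > nrow(usable))
    stop("n_match (", n_match, ") exceeds available SNP-SNP pairs (",
         nrow(usable), ")")
  if (!is.null(seed)) set.seed(seed)
  bin_all <- cut(usable$distance, breaks = bins, include.lowest = TRUE)
  nb <- nlevels(bin_all)
  means <- matrix(NA_real_, n_draws, nb)
  counts <- matrix(0, n_draws, nb)
  for (d in seq_len(n_draws)) {
    idx <- sample.int(nrow(usable), n_match)
    for (b in seq_len(nb)) {
      sel <- idx[!is.na(bin_all[idx]) & bin_all[idx] == levels(bin_all)[b]]
      counts[d, b] <- length(sel)
      if (length(sel)) means[d, b] <- mean(usable$r2[sel])
    }
  }
  data.frame(bin_lo = head(bins, -1), bin_hi = bins[-1],
             mean_r2 = colMeans(means, na.rm = TRUE),
             sd_r2 = apply(means, 2, stats::sd, na.rm = TRUE),
             mean_count = colMeans(counts))
}

#' All SNP-SNP pairs within a window
#'
#' Convenience builder of the SNP-SNP comparison set: every pair of distinct
#' SNP loci on the same chromosome within `window` bp.
#'
#' @param snps a [GenotypeMatrix].
#' @param window maximum inter-marker distance (bp, inclusive).
#' @return data.frame: `id_a`, `id_b`, `distance`, `r2`.
#' @export
snpSnpPairs <- function(snps, window = 100000L) {
  sl <- loci(snps)
  d <- dosages(snps)
  idx <- which(!sl$is_cnv)
  res <- list()
  for (ai in seq_along(idx)) {
    i <- idx[ai]
    rest <- idx[-seq_len(ai)]
    cand <- rest[sl$chrom[rest] == sl$chrom[i] &
                   abs(sl$pos[rest] - sl$pos[i]) <= window]
    if (!length(cand)) next
    res[[length(res) + 1L]] <- data.frame(
      id_a = sl$locus_id[i], id_b = sl$locus_id[cand],
      distance = abs(sl$pos[cand] - sl$pos[i]),
      r2 = vapply(cand, function(j) pairwiseR2(d[i, ], d[j, ]), numeric(1)))
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      distance = integer(), r2 = numeric())
  rownames(out) <- NULL
  out
}
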