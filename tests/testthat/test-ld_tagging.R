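test_that("dosage conversion is exact and length-preserving", {
  expect_equal(dosageFromGenotypes(c("0/0", "0/1", "1/1")), c(0L, 1L, 2L))
  expect_equal(dosageFromGenotypes(c("./.", "./.")),
               c(NA_integer_, NA_integer_))
  expect_equal(length(dosageFromGenotypes(rep("0/1", 7))), 7L)
})

test_that("composite r2 equals squared Pearson correlation", {
  expect_equal(pairwiseR2(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2)), 1.0)
  # perfect negative correlation squares to 1
  expect_equal(pairwiseR2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)), 1.0)
  a <- c(0, 1, 2, 0, 1, 2, 0, 0)
  b <- c(0, 1, 1, 0, 2, 2, 0, 1)
  expect_equal(pairwiseR2(a, b), oracle_r2(a, b), tolerance = 1e-12)
  # missing values drop pairwise; monomorphic after removal is undefined
  expect_equal(pairwiseR2(c(0, 1, NA, 2), c(1, 1, 0, 2)),
               oracle_r2(c(0, 1, NA, 2), c(1, 1, 0, 2)))
  expect_true(is.na(pairwiseR2(c(1, 1, 1, NA), c(0, 1, 2, 2))))
  expect_true(is.na(pairwiseR2(c(0, 1), c(0, NA))))
})

test_that("r2 is symmetric and bounded on random dosage pairs", {
  set.seed(41)
  for (k in 1:200) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    r <- pairwiseR2(a, b)
    expect_equal(r, pairwiseR2(b, a))
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("CNV-SNP pairing respects the window and interval exclusion", {
  sites <- data.frame(site_id = "cnv1", chrom = "chr1", pos = 200000L,
                      end = 210000L, svtype = "DEL", svlen = -10001L)
  gtc <- matrix(c(0L, 1L, 2L, 1L, 0L, 1L), 1)
  x <- make_cohort(sites, gtc, samples = sprintf("S%d", 1:6))
  snp_pos <- c(150000L,  # 50 kb left of pos -> kept, distance 50000
               205000L,  # inside the CNV -> removed
               99999L,   # 100,001 bp from pos -> outside the window
               310000L,  # exactly 100 kb right of end -> kept (inclusive)
               205000L + 1e6)  # far away -> excluded
  dos <- matrix(sample(0:2, 5 * 6, replace = TRUE), 5)
  gm <- GenotypeMatrix(dos, loci = data.frame(
    locus_id = sprintf("snp%d", 1:5), chrom = "chr1", pos = snp_pos,
    is_cnv = FALSE), samples = sprintf("S%d", 1:6))
  pairs <- cnvSnpPairs(x, gm)
  expect_setequal(pairs$snp_id, c("snp1", "snp4"))
  expect_equal(pairs$distance[pairs$snp_id == "snp1"], 50000L)
  expect_equal(pairs$distance[pairs$snp_id == "snp4"], 100000L)
})

test_that("tagging fractions behave at the extremes and monotonically", {
  sim <- simulateSVCohort(small_config(target_r2_levels = 1.0,
                                       snp_per_cnv = 1L, seed = 31))
  pairs <- cnvSnpPairs(sim$cohort, sim$snps)
  tf <- taggingFraction(pairs)
  expect_equal(tf$overall, 1.0)  # every CNV has a perfect tag
  # threshold monotonicity
  expect_lte(taggingFraction(pairs, 0.9)$overall,
             taggingFraction(pairs, 0.8)$overall)
  # independent SNPs tag (almost) nothing
  sim0 <- simulateSVCohort(small_config(target_r2_levels = 0,
                                        snp_per_cnv = 1L, seed = 32))
  pairs0 <- cnvSnpPairs(sim0$cohort, sim0$snps)
  expect_lte(taggingFraction(pairs0)$overall, 0.05)
})

test_that("composite r2 matches haplotype counting on phased founders", {
  cfg <- small_config(seed = 35)
  sim <- simulateSVCohort(cfg)
  founders <- sim$pedigree$founders
  checked <- 0L
  for (id in names(sim$blocks)[seq_len(30)]) {
    blk <- sim$blocks[[id]]
    if (is.null(blk)) next
    snp_hap <- snpHaplotypeAtR2(blk$founder_haps, 1.0)
    # complete association: the composite (genotype) estimator and the
    # haplotype-counting estimator coincide exactly
    gt_cnv <- genotypes(sim$cohort)[id, founders]
    nf <- length(founders)
    gt_snp <- snp_hap[2 * seq_len(nf) - 1L] + snp_hap[2 * seq_len(nf)]
    expect_equal(pairwiseR2(gt_cnv, gt_snp),
                 oracle_hap_r2(blk$founder_haps, as.integer(snp_hap)),
                 tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("rare co-segregating haplotypes give r2 = 1 pairs", {
  # a rare CNV and a rare SNP on the same founder haplotype tag each other
  cfg <- simulationConfig(n_samples = 100, n_trios = 40, n_del = 25,
                          n_dup = 0, n_mcnv = 0, n_spurious = 0,
                          n_duplicate_pairs = 0, target_r2_levels = 1.0,
                          snp_per_cnv = 1L, af_beta = c(0.2, 6), seed = 37)
  sim <- simulateSVCohort(cfg)
  pairs <- cnvSnpPairs(sim$cohort, sim$snps)
  rare <- pairs[pairs$maf_cnv < 0.05, ]
  expect_gt(nrow(rare), 0)
  expect_true(all(abs(rare$r2 - 1) < 1e-9))
})

test_that("decay profiles aggregate and conserve pair counts", {
  pairs <- data.frame(distance = c(5e3, 15e3, 25e3, 28e3, 95e3),
                      r2 = c(0.9, 0.8, 0.5, 0.7, 0.1),
                      maf_cnv = c(0.2, 0.2, 0.2, 0.01, 0.2))
  prof <- ldDecayProfile(pairs)
  expect_equal(sum(prof$count), nrow(pairs))
  common_20_30 <- prof[prof$bin_lo == 20000 & prof$maf_class == "common", ]
  expect_equal(common_20_30$mean_r2, 0.5)
  rare_20_30 <- prof[prof$bin_lo == 20000 & prof$maf_class == "rare", ]
  expect_equal(rare_20_30$mean_r2, 0.7)
  # all pairs in one bin: that bin's mean is the grand mean
  one <- data.frame(distance = rep(5e3, 4), r2 = c(0.1, 0.2, 0.3, 0.4))
  prof <- ldDecayProfile(one)
  expect_equal(prof$mean_r2[prof$bin_lo == 0], mean(one$r2))
  # constructed decay is recovered as non-increasing bin means
  set.seed(43)
  d <- runif(500, 0, 1e5)
  decay <- data.frame(distance = d, r2 = pmax(0, 1 - d / 1e5 + rnorm(500, 0, 0.02)))
  prof <- ldDecayProfile(decay)
  expect_true(all(diff(prof$mean_r2) < 0.05))
})

test_that("matched resampling is deterministic with exact edge cases", {
  set.seed(45)
  pairs <- data.frame(distance = runif(200, 0, 1e5), r2 = runif(200))
  # a single draw of everything has zero SD and the full-set mean
  full <- matchedSnpResampling(pairs, n_match = 200, n_draws = 1, seed = 1)
  prof <- ldDecayProfile(pairs[c("distance", "r2")])
  expect_equal(full$mean_r2, prof$mean_r2[prof$maf_class == "all"],
               tolerance = 1e-12)
  expect_true(all(full$sd_r2[!is.na(full$sd_r2)] == 0))
  # determinism under a fixed seed
  a <- matchedSnpResampling(pairs, 50, n_draws = 20, seed = 7)
  b <- matchedSnpResampling(pairs, 50, n_draws = 20, seed = 7)
  expect_identical(a, b)
  # resampled means agree with the full-set mean within sampling error
  r <- matchedSnpResampling(pairs, 100, n_draws = 400, seed = 9)
  se <- r$sd_r2 / sqrt(400)
  ok <- !is.na(r$mean_r2) & !is.na(prof$mean_r2[prof$maf_class == "all"])
  expect_true(all(abs(r$mean_r2 - prof$mean_r2[prof$maf_class == "all"])[ok]
                  <= 3 * se[ok] + 1e-12))
  expect_error(matchedSnpResampling(pairs, 201), "exceeds")
})

test_that("genotype corruption degrades CNV-SNP LD", {
  sim <- simulateSVCohort(small_config(target_r2_levels = 1.0,
                                       snp_per_cnv = 1L, seed = 47))
  pairs_clean <- cnvSnpPairs(sim$cohort, sim$snps)
  # corrupt 10% of CNV genotypes (lenient-style miscalls), same depth
  gt <- genotypes(sim$cohort)
  set.seed(48)
  hit <- matrix(runif(length(gt)) < 0.1, nrow(gt))
  hit[is.na(gt)] <- FALSE
  gt[hit] <- (gt[hit] + sample(1:2, sum(hit), replace = TRUE)) %% 3L
  corrupted <- SVCohort(
    data.frame(site_id = siteIDs(sim$cohort),
               chrom = as.character(GenomicRanges::seqnames(
                 SummarizedExperiment::rowRanges(sim$cohort))),
               pos = GenomicRanges::start(SummarizedExperiment::rowRanges(sim$cohort)),
               end = GenomicRanges::end(SummarizedExperiment::rowRanges(sim$cohort)),
               svtype = svType(sim$cohort),
               svlen = SummarizedExperiment::rowData(sim$cohort)$svlen),
    gt, dhffc(sim$cohort), dhbfc(sim$cohort),
    samples = colnames(sim$cohort))
  pairs_bad <- cnvSnpPairs(corrupted, sim$snps)
  expect_lt(mean(pairs_bad$r2, na.rm = TRUE),
            mean(pairs_clean$r2, na.rm = TRUE))
})
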