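test_that("trio classification matches transmission logic", {
  expect_equal(trioMendelianError(0L, 0L, 1L), "error")
  expect_equal(trioMendelianError(2L, 0L, 1L), "consistent")
  expect_equal(trioMendelianError(2L, 0L, 0L), "error")
  for (o in 0:2) expect_equal(trioMendelianError(1L, 1L, o), "consistent")
  expect_equal(trioMendelianError(NA, 1L, 2L), "uninformative")
  # vectorised call
  expect_equal(trioMendelianError(c(0L, 2L), c(0L, 2L), c(2L, 0L)),
               c("error", "error"))
})

# cohort with a prescribed number of erroring trios at one site
errors_cohort <- function(n_trios, n_errors, n_missing_trios = 0) {
  samples <- c(sprintf("F%03d", 1:n_trios), sprintf("M%03d", 1:n_trios),
               sprintf("O%03d", 1:n_trios))
  trios <- data.frame(offspring = sprintf("O%03d", 1:n_trios),
                      father = sprintf("F%03d", 1:n_trios),
                      mother = sprintf("M%03d", 1:n_trios))
  gt <- rep(0L, 3 * n_trios)
  names(gt) <- samples
  # an erroring trio: parents 0/0 x 0/0 with offspring 0/1
  gt[sprintf("O%03d", seq_len(n_errors))] <- 1L
  # carrier (but consistent) trios so the effective denominator is defined
  gt[sprintf("F%03d", seq(n_errors + 1, length.out = 5))] <- 1L
  gt[sprintf("O%03d", seq(n_errors + 1, length.out = 5))] <- 1L
  if (n_missing_trios > 0)
    gt[sprintf("M%03d", n_trios - seq_len(n_missing_trios) + 1)] <- NA
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 1000L,
                      end = 2000L, svtype = "DEL", svlen = -1001L)
  x <- make_cohort(sites, matrix(gt, 1, dimnames = list(NULL, samples)),
                   samples = samples)
  list(cohort = x, trios = trios)
}

test_that("error fractions reproduce the fixed-denominator convention", {
  ec <- errors_cohort(127, 15)
  mf <- mendelianErrorFraction(ec$cohort, ec$trios, "all_trios")
  expect_equal(mf$n_errors, 15)
  expect_equal(mf$fraction, 15 / 127)
  expect_equal(round(mf$fraction, 2), 0.12)  # reported at 2 decimals
  ec <- errors_cohort(127, 10)
  mf <- mendelianErrorFraction(ec$cohort, ec$trios, "all_trios")
  expect_equal(round(mf$fraction, 2), 0.08)
  # zero errors -> 0 in both modes
  ec <- errors_cohort(127, 0)
  expect_equal(
    mendelianErrorFraction(ec$cohort, ec$trios, "all_trios")$fraction, 0)
  expect_equal(
    mendelianErrorFraction(ec$cohort, ec$trios, "effective_trios")$fraction, 0)
})

test_that("the effective denominator counts only carrier trios", {
  ec <- errors_cohort(127, 15)
  eff <- mendelianErrorFraction(ec$cohort, ec$trios, "effective_trios")
  # carriers: the 15 erroring trios (offspring 0/1) + 5 consistent carriers
  expect_equal(eff$n_trios, 20)
  expect_equal(eff$fraction, 15 / 20)
  # missing-member trios leave the fixed denominator untouched but cannot
  # contribute errors; effective mode drops them from both
  ec <- errors_cohort(127, 15, n_missing_trios = 10)
  a <- mendelianErrorFraction(ec$cohort, ec$trios, "all_trios")
  expect_equal(a$n_trios, 127)
  # a non-carrier site yields NA in effective mode
  samples <- c("F1", "M1", "O1")
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 1L, end = 100L,
                      svtype = "DEL", svlen = -100L)
  x <- make_cohort(sites, matrix(c(0L, 0L, 0L), 1), samples = samples)
  trios <- data.frame(offspring = "O1", father = "F1", mother = "M1")
  expect_true(is.na(
    mendelianErrorFraction(x, trios, "effective_trios")$fraction))
})

test_that("fractions are invariant under trio order and parent swap", {
  sim <- simulateSVCohort(small_config(genotyping_error_rate = 0.05,
                                       seed = 17))
  trios <- sim$pedigree$trios
  base <- mendelianErrorFraction(sim$cohort, trios)
  shuffled <- mendelianErrorFraction(sim$cohort, trios[sample(nrow(trios)), ])
  expect_equal(base$fraction, shuffled$fraction)
  swapped <- trios
  swapped$father <- trios$mother; swapped$mother <- trios$father
  expect_equal(base$fraction,
               mendelianErrorFraction(sim$cohort, swapped)$fraction)
})

test_that("error fractions track the simulated genotyping error rate", {
  rates <- c(0, 0.02, 0.1)
  mean_frac <- vapply(rates, function(e) {
    sim <- simulateSVCohort(small_config(genotyping_error_rate = e,
                                         seed = 19))
    mean(mendelianErrorFraction(sim$cohort, sim$pedigree$trios)$fraction)
  }, numeric(1))
  expect_equal(mean_frac[1], 0)  # exactly 0 without errors
  expect_true(all(diff(mean_frac) > 0))  # monotone in the error rate
  # effective-mode fraction >= all-trios fraction wherever errors occur
  sim <- simulateSVCohort(small_config(genotyping_error_rate = 0.1,
                                       seed = 23))
  a <- mendelianErrorFraction(sim$cohort, sim$pedigree$trios, "all_trios")
  e <- mendelianErrorFraction(sim$cohort, sim$pedigree$trios,
                              "effective_trios")
  has_err <- a$n_errors > 0
  expect_true(all(e$fraction[has_err] >= a$fraction[has_err]))
})

test_that("site frequency spectra conserve site counts", {
  sim <- simulateSVCohort(small_config(seed = 25))
  sfs <- siteFrequencySpectrum(sim$cohort)
  expect_equal(sum(sfs$count[sfs$svtype == "ALL"]), nrow(sim$cohort))
  by_type <- sum(sfs$count[sfs$svtype != "ALL"])
  expect_equal(by_type, nrow(sim$cohort))
  # ten singleton sites land in the lowest AF bin
  samples <- sprintf("S%03d", 1:266)
  gt <- matrix(0L, 10, 266, dimnames = list(NULL, samples))
  gt[, 1] <- 1L  # one het carrier -> AF = 1/532
  sites <- data.frame(site_id = sprintf("s%d", 1:10), chrom = "chr1",
                      pos = seq(1e3, 1e5, length.out = 10),
                      end = seq(1e3, 1e5, length.out = 10) + 500,
                      svtype = "DEL", svlen = -501L)
  x <- make_cohort(sites, gt, samples = samples)
  sfs <- siteFrequencySpectrum(x)
  low <- sfs[sfs$svtype == "ALL" & sfs$bin_lo == 0, ]
  expect_equal(low$count, 10L)
  # a hypothetical all-het site sits at AF 0.5
  af <- alleleFrequencies(one_site_cohort("DEL", c(1L, 1L, 1L, 1L),
                                          rep(0.5, 4)))
  expect_equal(af$af, 0.5)
})

test_that("breakpoint resolution counts zero-width intervals as resolved", {
  sites <- data.frame(
    site_id = sprintf("s%d", 1:4), chrom = "chr1",
    pos = c(1e3, 2e3, 3e3, 4e3), end = c(1e3, 2e3, 3e3, 4e3) + 500,
    svtype = "DEL", svlen = -501L,
    cipos1 = c(NA, 0L, -10L, 0L), cipos2 = c(NA, 0L, 10L, 0L),
    ciend1 = c(NA, 0L, NA, -5L), ciend2 = c(NA, 0L, NA, 5L))
  gt <- matrix(1L, 4, 3)
  x <- make_cohort(sites, gt)
  res <- breakpointResolutionSummary(x)
  # absent CIs and explicit zero-width CIs are resolved; s3, s4 are not
  expect_equal(res$n_resolved, 2L)
  expect_equal(res$fraction, 0.5)
  # 68 of 100 resolved -> 0.68
  sites <- data.frame(site_id = sprintf("s%d", 1:100), chrom = "chr1",
                      pos = 1000L * (1:100), end = 1000L * (1:100) + 100L,
                      svtype = "DEL", svlen = -101L,
                      cipos1 = c(rep(NA, 68), rep(-5L, 32)),
                      cipos2 = c(rep(NA, 68), rep(5L, 32)),
                      ciend1 = NA, ciend2 = NA)
  x <- make_cohort(sites, matrix(1L, 100, 2))
  expect_equal(breakpointResolutionSummary(x)$fraction, 0.68)
})

test_that("per-sample counts match a direct recount", {
  sim <- simulateSVCohort(small_config(seed = 27))
  res <- perSampleCounts(sim$cohort)
  gt <- genotypes(sim$cohort)
  # brute-force recount per sample
  for (s in sample(colnames(gt), 10)) {
    want <- sum(gt[, s] %in% c(1L, 2L))
    got <- res$per_sample$count[res$per_sample$sample == s &
                                  res$per_sample$svtype == "ALL"]
    expect_equal(got, want)
  }
  all_counts <- colSums(!is.na(gt) & gt > 0L)
  expect_equal(unname(res$median["ALL"]), median(all_counts))
  # sample with no carried variant counts zero
  samples <- c("A", "B")
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 1L, end = 100L,
                      svtype = "DEL", svlen = -100L)
  x <- make_cohort(sites, matrix(c(0L, 1L), 1), samples = samples)
  res <- perSampleCounts(x)
  expect_equal(res$per_sample$count[res$per_sample$sample == "A" &
                                      res$per_sample$svtype == "ALL"], 0)
})
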