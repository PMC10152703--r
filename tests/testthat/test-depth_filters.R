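test_that("basic site filters apply size, polymorphism and all-het rules", {
  sites <- data.frame(
    site_id = sprintf("s%d", 1:6), chrom = "chr1",
    pos = c(1, 1000, 2000, 3000, 4000, 5000) * 100L,
    end = c(49, 1049, 2150, 3150, 4150, 5150) * 100L,
    svtype = "DEL",
    svlen = c(-49L, -50L, -500L, -500L, -500L, -500L))
  sites$end <- sites$pos + abs(sites$svlen) - 1L
  gt <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L),
              c(0L, 0L, 0L),             # all hom-ref -> non-polymorphic
              c(2L, 2L, NA),             # all hom-alt -> non-polymorphic
              c(1L, 1L, 1L),             # all het -> assembly artefact
              c(NA, NA, NA))             # no calls at all
  x <- make_cohort(sites, gt)
  expect_warning(res <- basicSiteFilters(x), "zero non-missing")
  expect_setequal(siteIDs(res$retained), "s2")
  led <- res$ledger
  expect_equal(led$reason[led$site_id == "s1"], "TOO_SMALL")  # 49 < 50
  expect_equal(led$reason[led$site_id == "s3"], "NON_POLYMORPHIC")
  expect_equal(led$reason[led$site_id == "s4"], "NON_POLYMORPHIC")
  expect_equal(led$reason[led$site_id == "s5"], "ALL_HET")
  expect_equal(led$reason[led$site_id == "s6"], "NON_POLYMORPHIC")
})

test_that("group statistics are computed over non-missing calls only", {
  x <- one_site_cohort("DEL", gt = c(0L, 1L, 1L, NA),
                       fold = c(1.0, 0.5, 0.6, 0.9))
  st <- groupStats(x, "s1", "dhffc")
  expect_equal(unname(st$n), c(1, 2, 0))
  expect_equal(unname(st$mean[1:2]), c(1.0, 0.55))
  expect_equal(unname(st$min["g1"]), 0.5)
  expect_equal(unname(st$max["g1"]), 0.6)
  expect_true(is.na(st$mean["g2"]))  # absent when the group is empty
  # depth value missing for a genotyped sample is an error naming both
  y <- one_site_cohort("DEL", gt = c(0L, 1L), fold = c(1.0, NA))
  expect_error(groupStats(y, 1, "dhffc"), "S02")
})

test_that("deletion depth rules reproduce the published decision logic", {
  # published group means: 0.91 vs 0.55 -> ratio 1.65 passes
  st <- makeGroupStats(n = c(10, 5, 0), mean = c(0.91, 0.55, NA),
                       min = c(0.8, 0.4, NA), max = c(1.1, 0.7, NA))
  expect_true(deletionDepthFilter(st)$pass)
  # spurious site: no depth change between genotype groups
  st <- makeGroupStats(n = c(10, 5, 0), mean = c(1.0, 1.0, NA),
                       min = c(0.9, 0.9, NA), max = c(1.1, 1.1, NA))
  res <- deletionDepthFilter(st)
  expect_false(res$pass)
  expect_equal(res$failing, "DEPTH_RULE_DEL_a")
  # zero heterozygote mean fails rule (b), not (a)
  st <- makeGroupStats(n = c(10, 5, 0), mean = c(0.91, 0, NA),
                       min = c(0.8, 0, NA), max = c(1.1, 0, NA))
  expect_equal(deletionDepthFilter(st)$failing, "DEPTH_RULE_DEL_b")
  # homozygous-only site: the 1/1 group stands in for 0/1
  st <- makeGroupStats(n = c(10, 0, 4), mean = c(0.91, NA, 0.03),
                       min = c(0.8, NA, 0), max = c(1.1, NA, 0.1))
  expect_true(deletionDepthFilter(st)$pass)
  st <- makeGroupStats(n = c(10, 0, 4), mean = c(0.91, NA, 1.4),
                       min = c(0.8, NA, 1.35), max = c(1.1, NA, 1.45))
  expect_false(deletionDepthFilter(st)$pass)  # stand-in group hits rule (d)
})

test_that("duplication depth rules use the pooled carrier mean", {
  st <- makeGroupStats(n = c(10, 4, 0), mean = c(1.0, 1.3, NA),
                       min = c(0.9, 1.1, NA), max = c(1.1, 1.5, NA))
  expect_true(duplicationDepthFilter(st)$pass)
  # pooled mean, not mean of group means: 4 calls at 1.22 + 2 at 1.45
  st <- makeGroupStats(n = c(10, 4, 2), mean = c(1.0, 1.22, 1.45),
                       min = c(0.9, 1.1, 1.4), max = c(1.1, 1.3, 1.5))
  res <- duplicationDepthFilter(st)
  expect_true(res$pass)  # pooled (4*1.22 + 2*1.45)/6 = 1.2967 -> ratio ok
  st <- makeGroupStats(n = c(10, 1, 1), mean = c(1.0, 6.0, 6.0),
                       min = c(0.9, 6.0, 6.0), max = c(1.1, 6.0, 6.0))
  expect_equal(duplicationDepthFilter(st)$failing, "DEPTH_RULE_DUP_a")
  st <- makeGroupStats(n = c(10, 4, 0), mean = c(1.0, 1.3, NA),
                       min = c(0.3, 1.1, NA), max = c(1.1, 1.5, NA))
  expect_equal(duplicationDepthFilter(st)$failing, "DEPTH_RULE_DUP_b")
})

test_that("depth decisions are invariant under sample permutation", {
  sim <- simulateSVCohort(small_config(seed = 14))
  x <- sim$cohort
  perm <- sample(ncol(x))
  y <- x[, perm]
  fx <- runFilterCascade(x)
  fy <- runFilterCascade(y)
  expect_setequal(siteIDs(fx$clean), siteIDs(fy$clean))
  expect_equal(sort(fx$ledger$site_id), sort(fy$ledger$site_id))
})

dup_sites <- function(coords, svtype = "DEL") {
  data.frame(site_id = sprintf("s%d", seq_len(nrow(coords))), chrom = "chr1",
             pos = coords[, 1], end = coords[, 2], svtype = svtype,
             svlen = (coords[, 2] - coords[, 1] + 1L) *
               ifelse(svtype == "DEL", -1L, 1L))
}

test_that("duplicate collapsing follows the reciprocal-overlap contract", {
  # [1000,2000] vs [1010,2010]: overlap 991/1001 = 0.990 both ways
  sites <- dup_sites(rbind(c(1000L, 2000L), c(1010L, 2010L)))
  gt <- rbind(c(0L, 1L, 1L), c(0L, 1L, NA))
  x <- make_cohort(sites, gt)
  res <- collapseDuplicateCalls(x)
  expect_equal(res$removed_ids, "s2")  # fewer calls loses
  # same coordinates, different svtype: both kept
  sites <- rbind(dup_sites(rbind(c(1000L, 2000L))),
                 dup_sites(rbind(c(1000L, 2000L)), "DUP"))
  sites$site_id <- c("a", "b")
  x <- make_cohort(sites, rbind(c(0L, 1L), c(0L, 1L)))
  expect_equal(length(collapseDuplicateCalls(x)$removed_ids), 0L)
  # reciprocal overlap 0.90: below threshold, both kept
  sites <- dup_sites(rbind(c(1000L, 1999L), c(1100L, 2099L)))
  x <- make_cohort(sites, rbind(c(0L, 1L), c(0L, 1L)))
  expect_equal(length(collapseDuplicateCalls(x)$removed_ids), 0L)
  expect_equal(length(collapseDuplicateCalls(x, 0.90)$removed_ids), 1L)
})

test_that("collapsing agrees with the all-pairs oracle on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15L
    pos <- as.integer(sample(1000:20000, n))
    len <- as.integer(sample(c(100, 101, 105, 1000, 1050), n, replace = TRUE))
    sites <- data.frame(site_id = sprintf("s%02d", 1:n), chrom = "chr1",
                        pos = pos, end = pos + len - 1L,
                        svtype = sample(c("DEL", "DUP"), n, replace = TRUE))
    sites$svlen <- (sites$end - sites$pos + 1L) *
      ifelse(sites$svtype == "DEL", -1L, 1L)
    gt <- matrix(sample(c(0:2, NA), n * 6, replace = TRUE), n)
    x <- make_cohort(sites, gt)
    got <- sort(collapseDuplicateCalls(x)$removed_ids)
    want <- oracle_collapse(sites, rowSums(!is.na(gt)))
    expect_identical(got, want)
    # monotonicity: a stricter threshold never collapses more
    for (thr in c(0.95, 0.97, 0.99, 1.0)) {
      n_thr <- length(collapseDuplicateCalls(x, thr)$removed_ids)
      if (exists("prev_n")) expect_lte(n_thr, prev_n)
      prev_n <- n_thr
    }
    rm(prev_n)
  }
})

test_that("the cascade ledger conserves counts at every step", {
  sim <- simulateSVCohort(small_config(seed = 5))
  filt <- runFilterCascade(sim$cohort)
  s <- filt$summary
  expect_true(all(s$input == s$removed + s$retained))
  # chaining: retained counts at one step feed the next step's input
  for (tp in c("DEL", "DUP")) {
    st <- s[s$svtype == tp, ]
    expect_true(all(head(st$retained, -1) == st$input[-1]))
  }
  # the ledger holds every removed site exactly once
  expect_false(any(duplicated(filt$ledger$site_id)))
  expect_equal(nrow(sim$cohort), nrow(filt$clean) + nrow(filt$ledger))
  expect_true(all(filt$ledger$reason %in% c(
    "TYPE_EXCLUDED", "TOO_SMALL", "NON_POLYMORPHIC", "ALL_HET",
    paste0("DEPTH_RULE_DEL_", letters[1:5]),
    paste0("DEPTH_RULE_DUP_", letters[1:3]), "DUPLICATE_CALL")))
})

test_that("call-set comparison matches by reciprocal overlap, greedily", {
  sites <- dup_sites(rbind(c(100L, 200L), c(5000L, 6000L)))
  x <- make_cohort(sites, rbind(c(0L, 1L), c(0L, 1L)))
  # identical sets: every record matched
  res <- callsetReciprocalOverlap(x, x)
  expect_equal(nrow(res$pairs), 2L)
  # disjoint chromosomes: zero matches
  sites2 <- sites; sites2$chrom <- "chr9"
  y <- make_cohort(sites2, rbind(c(0L, 1L), c(0L, 1L)))
  expect_equal(nrow(callsetReciprocalOverlap(x, y)$pairs), 0L)
  # [100,200] vs [105,205]: overlap 96/101 = 0.9505 both ways -> matched
  sites3 <- dup_sites(rbind(c(105L, 205L)))
  z <- make_cohort(sites3, matrix(c(0L, 1L), 1))
  res <- callsetReciprocalOverlap(x, z, 0.95)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$overlap, 96 / 101, tolerance = 1e-12)
})
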