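# Independent oracles and fixture builders. Everything here is deliberately
# written against first principles (sums, enumeration, all-pairs scans), not
# by calling the code paths it checks.

# squared Pearson correlation from raw sums
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  if (den == 0) return(NA_real_)
  num^2 / den
}

# classical 2x2 haplotype-counting r2
oracle_hap_r2 <- function(ha, hb) {
  H <- length(ha)
  pA <- sum(ha) / H; pB <- sum(hb) / H
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- sum(ha == 1 & hb == 1) / H
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Mendelian check by exhaustive transmission enumeration
oracle_mendel <- function(f, m, o) {
  if (anyNA(c(f, m, o))) return("uninformative")
  gam <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  for (a in gam(f)) for (b in gam(m)) if (a + b == o) return("consistent")
  "error"
}

# all-pairs duplicate clustering by reciprocal overlap (for small fixtures)
oracle_collapse <- function(sites, ncalls, thr = 0.95) {
  n <- nrow(sites)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sites$svtype[i] != sites$svtype[j]) next
    if (sites$chrom[i] != sites$chrom[j]) next
    ov <- min(sites$end[i], sites$end[j]) - max(sites$pos[i], sites$pos[j]) + 1
    if (ov <= 0) next
    la <- sites$end[i] - sites$pos[i] + 1
    lb <- sites$end[j] - sites$pos[j] + 1
    if (ov / la >= thr && ov / lb >= thr) adj[i, j] <- adj[j, i] <- TRUE
  }
  seen <- rep(FALSE, n)
  removed <- character()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      grow <- which(apply(adj[, comp, drop = FALSE], 1, any) &
                      !seq_len(n) %in% comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    seen[comp] <- TRUE
    if (length(comp) > 1) {
      ord <- order(-ncalls[comp], sites$pos[comp], sites$site_id[comp])
      removed <- c(removed, sites$site_id[comp[ord][-1]])
    }
  }
  sort(removed)
}

# gap-based cluster counting: valid for tight clusters separated by wide
# gaps (cluster sd << gap), independent of any density estimate
oracle_modes_gap <- function(values, min_gap = 0.2, min_size = 5L) {
  v <- sort(values)
  cluster <- cumsum(c(0, diff(v) > min_gap))
  sum(table(cluster) >= min_size)
}

# tiny SVCohort builder: one row per site description
make_cohort <- function(sites, gt, dhffc = NULL, dhbfc = NULL,
                        samples = NULL) {
  gt <- as.matrix(gt)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(gt)))
  colnames(gt) <- samples
  SVCohort(sites, gt, dhffc, dhbfc, samples = samples)
}

# one-site cohort with explicit per-sample genotypes and depth
one_site_cohort <- function(svtype, gt, fold, pos = 1000L, end = 2000L,
                            svlen = NULL) {
  if (is.null(svlen)) svlen <- (end - pos + 1L) * if (svtype == "DEL") -1L else 1L
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = pos, end = end,
                      svtype = svtype, svlen = svlen)
  m <- matrix(fold, nrow = 1)
  make_cohort(sites, matrix(as.integer(gt), nrow = 1), m, m)
}

small_config <- function(...) {
  simulationConfig(n_samples = 80L, n_trios = 30L, n_del = 40L, n_dup = 15L,
                   n_mcnv = 1L, n_spurious = 8L, n_duplicate_pairs = 3L, ...)
}
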