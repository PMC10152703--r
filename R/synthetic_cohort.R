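## Pedigree-aware synthetic SV cohort generator.
##
## The generator emulates the statistical structure the curation pipeline
## assumes: a family cohort (founders + trios), biallelic CNV loci whose
## read-depth fold-coverage is conditional on the true copy number, injected
## spurious sites with no depth change, redundant duplicate calls,
## multi-allelic loci with more than three depth modes, and SNPs placed on
## founder haplotypes in tunable LD with the CNV allele. Fold-coverage noise
## is a normal truncated (censored) at zero; no distributional claim beyond
## that is made.

#' Simulation configuration
#'
#' Defaults describe the cohort the pipeline targets: 266 samples forming 127
#' trios; deletion fold-coverage means 0.91 / 0.55 / 0.03 for 0/0, 0/1 and
#' 1/1; duplication means 1.0 / 1.22 / 1.45; a rare-skewed Beta
#' allele-frequency spectrum; multi-allelic loci with haploid copy numbers
#' {1, 4, 5, 6}.
#'
#' @param n_samples cohort size (founders + trio offspring).
#' @param n_trios number of parent-parent-offspring trios; founders number
#'   `n_samples - n_trios` and parents are drawn from the founders, so parents
#'   may be shared between trios.
#' @param n_del,n_dup number of biallelic deletion / duplication sites.
#' @param n_mcnv number of multi-allelic CNV loci.
#' @param n_spurious number of spurious sites (depth ~ 1 for every sample).
#' @param n_duplicate_pairs number of redundant duplicate call pairs.
#' @param n_lenient number of clean sites receiving injected genotype/depth
#'   discordance (lenient-style corruption).
#' @param lenient_discordance fraction of samples whose reported genotype is
#'   re-drawn at an injected lenient site.
#' @param del_fold_means,dup_fold_means genotype-conditional fold-coverage
#'   means for (0/0, 0/1, 1/1).
#' @param fold_sd standard deviation of fold-coverage noise (fold units).
#' @param depth_cor correlation between the DHFFC and DHBFC noise.
#' @param af_beta shape parameters of the Beta allele-frequency distribution
#'   (rare-skewed by default).
#' @param af_min lower truncation of simulated allele frequencies.
#' @param genotyping_error_rate probability a reported genotype is corrupted
#'   (uniform over the other two states).
#' @param mcnv_allele_cns haploid copy-number set of multi-allelic loci.
#' @param mcnv_allele_probs allele probabilities matching `mcnv_allele_cns`.
#' @param snp_per_cnv SNPs simulated per biallelic CNV.
#' @param target_r2_levels target founder-haplotype r2 values cycled over the
#'   SNPs of each CNV.
#' @param ld_window window around CNV breakpoints for SNP placement (bp).
#' @param single_base_fraction fraction of sites with single-base resolved
#'   breakpoints (zero-width / absent confidence intervals).
#' @param gene_fraction fraction of clean sites that receive an overlapping
#'   synthetic gene model.
#' @param seed integer seed; every run of [simulateSVCohort] with the same
#'   config is identical.
#' @return A validated config (list of class `sv_sim_config`).
#' @export
simulationConfig <- function(n_samples = 266L, n_trios = 127L,
                             n_del = 500L, n_dup = 100L, n_mcnv = 5L,
                             n_spurious = 50L, n_duplicate_pairs = 10L,
                             n_lenient = 0L, lenient_discordance = 0.1,
                             del_fold_means = c(0.91, 0.55, 0.03),
                             dup_fold_means = c(1.0, 1.22, 1.45),
                             fold_sd = 0.06, depth_cor = 0.8,
                             af_beta = c(0.3, 2.5), af_min = 0.005,
                             genotyping_error_rate = 0,
                             mcnv_allele_cns = c(1L, 4L, 5L, 6L),
                             mcnv_allele_probs = c(0.55, 0.18, 0.17, 0.10),
                             snp_per_cnv = 2L, target_r2_levels = c(1.0, 0.6),
                             ld_window = 100000L,
                             single_base_fraction = 0.68,
                             gene_fraction = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  n_founders <- n_samples - n_trios
  if (n_trios > 0 && n_founders < 2)
    stop("infeasible counts: need at least 2 founders (n_samples - n_trios)")
  if (n_founders < 1) stop("infeasible counts: no founders")
  probs <- c(lenient_discordance, genotyping_error_rate, single_base_fraction,
             gene_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.unsorted(rev(del_fold_means), strictly = TRUE))
    stop("del_fold_means must be strictly decreasing (0/0 > 0/1 > 1/1)")
  if (is.unsorted(dup_fold_means, strictly = TRUE))
    stop("dup_fold_means must be strictly increasing (0/0 < 0/1 < 1/1)")
  if (fold_sd <= 0) stop("fold_sd must be positive")
  if (length(mcnv_allele_cns) != length(mcnv_allele_probs) ||
      abs(sum(mcnv_allele_probs) - 1) > 1e-8)
    stop("mcnv_allele_probs must match mcnv_allele_cns and sum to 1")
  if (n_duplicate_pairs > n_del + n_dup || n_lenient > n_del + n_dup)
    stop("duplicate/lenient counts exceed the number of clean sites")
  if (any(target_r2_levels < 0 | target_r2_levels > 1))
    stop("target_r2_levels must lie in [0, 1]")
  cfg$n_founders <- as.integer(n_founders)
  class(cfg) <- "sv_sim_config"
  cfg
}

#' Generate a family pedigree
#'
#' Founders are unrelated; each trio draws a father from the male founders and
#' a mother from the female founders (with replacement, so parents can be
#' shared between trios, as in real half-sib cattle cohorts).
#'
#' @param config a [simulationConfig].
#' @param seed optional seed (defaults to `config$seed`).
#' @return list with `samples` (cohort order: founders then offspring),
#'   `founders`, and `trios` (data.frame offspring/father/mother).
#' @export
generatePedigree <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  nf <- config$n_founders
  founders <- sprintf("F%03d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  males <- founders[sex == "M"]; females <- founders[sex == "F"]
  nt <- config$n_trios
  if (nt > 0 && (!length(males) || !length(females)))
    stop("infeasible counts: need male and female founders")
  offspring <- if (nt > 0) sprintf("O%03d", seq_len(nt)) else character()
  trios <- data.frame(
    offspring = offspring,
    father = if (nt > 0) sample(males, nt, replace = TRUE) else character(),
    mother = if (nt > 0) sample(females, nt, replace = TRUE) else character())
  list(samples = c(founders, offspring), founders = founders, trios = trios)
}

#' Fold-coverage of a region given observed and reference depth
#'
#' A heterozygous deletion covered at 15X against 30X in flanking non-SV
#' sequence has fold-coverage 15/30 = 0.5; a duplicated region at 45X against
#' 30X has 1.5.
#'
#' @param depth_in_sv observed X-coverage inside the SV (>= 0).
#' @param depth_reference X-coverage of the reference region (> 0).
#' @return `depth_in_sv / depth_reference`.
#' @export
computeFoldCoverage <- function(depth_in_sv, depth_reference) {
  if (any(depth_reference <= 0)) stop("depth_reference must be positive")
  if (any(depth_in_sv < 0)) stop("depth_in_sv must be non-negative")
  depth_in_sv / depth_reference
}

#' Simulate per-sample fold-coverage from true copy number
#'
#' For biallelic sites the mean is the genotype-conditional configured mean;
#' for multi-allelic sites it is `cn / 2`. DHFFC and DHBFC are drawn with
#' correlated normal noise (`config$depth_cor`), censored at zero.
#'
#' @param true_diploid_cn integer vector of true diploid copy numbers.
#' @param svtype `"DEL"`, `"DUP"` or `"MCNV"`.
#' @param config a [simulationConfig].
#' @param seed optional seed.
#' @return list of numeric vectors `dhffc` and `dhbfc`.
#' @export
simulateFoldCoverage <- function(true_diploid_cn, svtype, config,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(true_diploid_cn < 0)) stop("copy numbers must be non-negative")
  mu <- switch(svtype,
    DEL = config$del_fold_means[pmin(pmax(2L - true_diploid_cn, 0L), 2L) + 1L],
    DUP = config$dup_fold_means[pmin(pmax(true_diploid_cn - 2L, 0L), 2L) + 1L],
    MCNV = true_diploid_cn / 2,
    stop("unsupported svtype: ", svtype))
  n <- length(mu)
  e1 <- rnorm(n, 0, config$fold_sd)
  e2 <- rnorm(n, 0, config$fold_sd)
  rho <- config$depth_cor
  list(dhffc = pmax(0, mu + e1),
       dhbfc = pmax(0, mu + rho * e1 + sqrt(1 - rho^2) * e2))
}

## ---- haplotype machinery (single-locus blocks, no recombination) ----

## One transmission pattern per site: which parental haplotype (1 or 2) each
## offspring receives from father and mother.
drawTransmission <- function(n_offspring) {
  list(father = sample(1:2, n_offspring, replace = TRUE),
       mother = sample(1:2, n_offspring, replace = TRUE))
}

## hap: vector of haplotype alleles, founder i owns entries 2i-1 and 2i.
## Returns per-sample summed allele values in cohort order.
sumHaplotypes <- function(hap, pedigree, trans) {
  nf <- length(pedigree$founders)
  fidx <- setNames(seq_len(nf), pedigree$founders)
  founder_val <- hap[2 * seq_len(nf) - 1L] + hap[2 * seq_len(nf)]
  if (nrow(pedigree$trios) == 0L)
    return(setNames(founder_val, pedigree$founders))
  fa <- fidx[pedigree$trios$father]; mo <- fidx[pedigree$trios$mother]
  off_val <- hap[2 * (fa - 1L) + trans$father] +
    hap[2 * (mo - 1L) + trans$mother]
  setNames(c(founder_val, off_val), pedigree$samples)
}

## Haplotype value an offspring inherited from each parent (needed for
## SNP/CNV co-transmission when alleles live on the same founder haplotype).
offspringHaps <- function(hap, pedigree, trans) {
  nf <- length(pedigree$founders)
  fidx <- setNames(seq_len(nf), pedigree$founders)
  fa <- fidx[pedigree$trios$father]; mo <- fidx[pedigree$trios$mother]
  cbind(hap[2 * (fa - 1L) + trans$father], hap[2 * (mo - 1L) + trans$mother])
}

#' Transmit a biallelic variant through a pedigree
#'
#' Founder haplotypes are Bernoulli(`allele_freq`) draws (Hardy-Weinberg);
#' each offspring receives one haplotype from each parent. Each reported
#' genotype is then independently corrupted with probability `error_rate`,
#' uniformly over the other two genotype states.
#'
#' @param pedigree list from [generatePedigree].
#' @param allele_freq allele frequency in (0, 1).
#' @param error_rate genotype corruption probability.
#' @param seed optional seed.
#' @return list with `dosage` (reported 0/1/2 per sample, cohort order),
#'   `true_dosage`, `founder_haps`, and `transmission`.
#' @export
transmitGenotypes <- function(pedigree, allele_freq, error_rate = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("allele_freq must lie in (0, 1)")
  hap <- rbinom(2L * length(pedigree$founders), 1L, allele_freq)
  trans <- drawTransmission(nrow(pedigree$trios))
  true_dosage <- sumHaplotypes(hap, pedigree, trans)
  list(dosage = corruptGenotypes(true_dosage, error_rate),
       true_dosage = true_dosage, founder_haps = hap, transmission = trans)
}

corruptGenotypes <- function(dosage, error_rate) {
  if (error_rate <= 0) return(dosage)
  hit <- runif(length(dosage)) < error_rate
  if (any(hit)) {
    dosage[hit] <- vapply(dosage[hit],
                          function(d) sample(setdiff(0:2, d), 1L), integer(1))
  }
  dosage
}

## r2 between two binary haplotype vectors from the 2x2 counts, O(1).
hapR2Counts <- function(n11, n1, n2, H) {
  num <- (n11 * H - n1 * n2)
  den <- n1 * (H - n1) * n2 * (H - n2)
  if (den == 0) return(NA_real_)
  num^2 / den
}

#' Place SNP alleles on founder haplotypes at a target r2 with a CNV
#'
#' Starting from perfect association (SNP allele identical to the CNV allele
#' on every founder haplotype), single-haplotype allele flips are applied
#' greedily until the realized founder-haplotype r2 is within `tol` of
#' `target_r2`. For rare CNVs intermediate targets can be unreachable (the r2
#' ladder is coarse); the best achievable assignment is then returned with a
#' warning.
#'
#' @param cnv_hap binary founder-haplotype vector of the CNV allele.
#' @param target_r2 target squared correlation in [0, 1].
#' @param tol acceptance tolerance on the realized r2.
#' @param seed optional seed (tie-breaking among equally good flips).
#' @return binary SNP haplotype vector with attribute `realized_r2`.
#' @export
snpHaplotypeAtR2 <- function(cnv_hap, target_r2, tol = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- length(cnv_hap)
  snp <- cnv_hap
  counts <- function(snp) c(n11 = sum(cnv_hap == 1 & snp == 1), n1 = sum(snp))
  n2 <- sum(cnv_hap)
  cc <- counts(snp)
  r2 <- hapR2Counts(cc["n11"], cc["n1"], n2, H)
  best <- list(snp = snp, r2 = r2)
  for (iter in seq_len(2L * H)) {
    if (!is.na(r2) && abs(r2 - target_r2) <= tol) break
    ## four flip classes: (cnv, snp) = (1,1)->(1,0), (1,0)->(1,1),
    ## (0,1)->(0,0), (0,0)->(0,1); effect on counts is O(1)
    cand <- list(c(-1L, -1L), c(1L, 1L), c(0L, -1L), c(0L, 1L))
    avail <- c(any(cnv_hap == 1 & snp == 1), any(cnv_hap == 1 & snp == 0),
               any(cnv_hap == 0 & snp == 1), any(cnv_hap == 0 & snp == 0))
    score <- vapply(seq_along(cand), function(k) {
      if (!avail[k]) return(NA_real_)
      n1new <- cc["n1"] + cand[[k]][2]
      if (n1new <= 0 || n1new >= H) return(NA_real_)  # keep SNP polymorphic
      r2new <- hapR2Counts(cc["n11"] + cand[[k]][1], n1new, n2, H)
      if (is.na(r2new)) NA_real_ else abs(r2new - target_r2)
    }, numeric(1))
    if (all(is.na(score))) break
    k <- which.min(score)
    if (!is.na(r2) && score[k] >= abs(r2 - target_r2)) break  # no improvement
    flip_from <- switch(k, `1` = cnv_hap == 1 & snp == 1,
                        `2` = cnv_hap == 1 & snp == 0,
                        `3` = cnv_hap == 0 & snp == 1,
                        `4` = cnv_hap == 0 & snp == 0)
    i <- which(flip_from)
    i <- if (length(i) > 1L) sample(i, 1L) else i
    snp[i] <- 1L - snp[i]
    cc <- counts(snp)
    r2 <- hapR2Counts(cc["n11"], cc["n1"], n2, H)
    if (is.na(best$r2) || abs(r2 - target_r2) < abs(best$r2 - target_r2))
      best <- list(snp = snp, r2 = r2)
  }
  if (is.na(best$r2) || abs(best$r2 - target_r2) > tol)
    warning(sprintf("target r2 %.2f unreachable; best achievable %.3f",
                    target_r2, ifelse(is.na(best$r2), NA, best$r2)))
  structure(best$snp, realized_r2 = unname(best$r2))
}

#' Simulate SNPs in tunable LD with a CNV site
#'
#' SNP alleles are placed on the founder haplotypes of the CNV's locus block
#' (see [snpHaplotypeAtR2]) and transmitted to offspring along the same
#' haplotypes (single-locus blocks, no recombination). Positions are uniform
#' within `window` bp of the CNV breakpoints, strictly outside the CNV.
#'
#' @param block site block from [simulateSVCohort] (`founder_haps`,
#'   `transmission`, `chrom`, `pos`, `end`, binary alleles).
#' @param target_r2 target founder-haplotype r2 (scalar or per-SNP vector).
#' @param n_snp number of SNPs.
#' @param pedigree list from [generatePedigree].
#' @param window placement window around breakpoints (bp).
#' @param prefix locus-id prefix.
#' @param seed optional seed.
#' @return A [GenotypeMatrix] of the new SNPs with per-locus
#'   `realized_r2` column in `loci()`.
#' @export
simulateLinkedSnps <- function(block, target_r2, n_snp = 1L, pedigree,
                               window = 100000L, prefix = "snp",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target_r2 <- rep_len(target_r2, n_snp)
  hap <- block$founder_haps
  dos <- matrix(NA_integer_, n_snp, length(pedigree$samples))
  posv <- integer(n_snp); rr <- numeric(n_snp)
  for (j in seq_len(n_snp)) {
    snp_hap <- snpHaplotypeAtR2(hap, target_r2[j])
    rr[j] <- attr(snp_hap, "realized_r2")
    dos[j, ] <- sumHaplotypes(as.integer(snp_hap), pedigree,
                              block$transmission)
    left <- runif(1) < 0.5
    posv[j] <- if (left) {
      max(1L, block$pos - sample.int(window, 1L))
    } else block$end + sample.int(window, 1L)
  }
  lid <- sprintf("%s_%s_%d", prefix, block$site_id, seq_len(n_snp))
  GenotypeMatrix(dos,
                 loci = data.frame(locus_id = lid, chrom = block$chrom,
                                   pos = posv, is_cnv = FALSE,
                                   realized_r2 = rr),
                 samples = pedigree$samples)
}

## Draw a segregating allele frequency + transmission; resample genotypes
## until the site is polymorphic in the finite cohort.
segregatingSite <- function(pedigree, config) {
  for (try in 1:50) {
    af <- rbeta(1, config$af_beta[1], config$af_beta[2])
    af <- min(max(af, config$af_min), 0.95)
    hap <- rbinom(2L * length(pedigree$founders), 1L, af)
    trans <- drawTransmission(nrow(pedigree$trios))
    dosage <- sumHaplotypes(hap, pedigree, trans)
    if (any(dosage > 0) && any(dosage < 2)) {
      return(list(af = af, founder_haps = hap, transmission = trans,
                  true_dosage = dosage))
    }
  }
  stop("failed to draw a segregating site; check af settings")
}

newSiteCoords <- function(state, len) {
  ## advance a per-chromosome cursor so locus blocks (CNV +/- 100 kb of SNPs)
  ## never overlap between sites
  gap <- 250000L
  state$cursor <- state$cursor + gap
  if (state$cursor > 120000000L) {
    state$chrom_i <- state$chrom_i + 1L
    state$cursor <- gap
  }
  list(state = state, chrom = paste0("chr", state$chrom_i),
       pos = state$cursor, end = state$cursor + len - 1L)
}

drawLength <- function() as.integer(round(10^runif(1, 1.7, 4.5)))

#' Inject artifact sites into a simulated call set
#'
#' Adds (a) spurious sites whose fold-coverage stays near 1.0 for every sample
#' regardless of genotype (genotypes still transmit through the pedigree, so
#' artifact sites carry no Mendelian signal of their own), (b) duplicate call
#' pairs whose breakpoints are jittered by at most 1.25% of the length per
#' endpoint, guaranteeing >= 95% reciprocal overlap, and (c) lenient-style
#' genotype/depth discordance on a configured number of clean sites. Truth
#' labels are recorded for every affected site.
#'
#' @param sim in-progress simulation (internal structure from
#'   [simulateSVCohort]); see that function.
#' @param config a [simulationConfig].
#' @param seed optional seed.
#' @return the augmented simulation list.
#' @export
injectArtifacts <- function(sim, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pedigree <- sim$pedigree
  ns <- length(pedigree$samples)
  ## (c) lenient-style corruption on existing clean sites
  if (config$n_lenient > 0L) {
    idx <- sample(which(sim$truth$tier %in% c("stringent", "lenient")),
                  config$n_lenient)
    for (i in idx) {
      hit <- runif(ns) < config$lenient_discordance
      if (!any(hit)) hit[sample.int(ns, 1L)] <- TRUE
      sim$gt[i, hit] <- vapply(sim$gt[i, hit], function(d)
        sample(setdiff(0:2, d), 1L), integer(1))
      sim$truth$tier[i] <- "lenient"
    }
  }
  ## (a) spurious sites: flat depth, pedigree-consistent genotypes
  for (k in seq_len(config$n_spurious)) {
    seg <- segregatingSite(pedigree, config)
    svtype <- if (k %% 2 == 0) "DUP" else "DEL"
    len <- drawLength()
    co <- newSiteCoords(sim$state, len); sim$state <- co$state
    id <- sprintf("spur%03d", k)
    fold <- simulateFoldCoverage(rep(2L, length(pedigree$samples)),
                                 if (svtype == "DEL") "DEL" else "DUP",
                                 replace(config,
                                         c("del_fold_means", "dup_fold_means"),
                                         list(c(1, 1 - 1e-9, 1 - 2e-9),
                                              c(1, 1 + 1e-9, 1 + 2e-9))))
    sim <- appendSite(sim, id, co, svtype, len,
                      setNames(rep(2L, ns), pedigree$samples),
                      corruptGenotypes(seg$true_dosage,
                                       config$genotyping_error_rate),
                      fold, tier = "spurious", af = seg$af,
                      block = list(site_id = id, chrom = co$chrom,
                                   pos = co$pos, end = co$end,
                                   founder_haps = seg$founder_haps,
                                   transmission = seg$transmission))
  }
  ## (b) duplicate pairs: jittered copies of existing clean sites
  ## (stringent sources preferred: they pass the depth rules robustly, so the
  ## pair reliably reaches the duplicate-collapse step)
  str_idx <- which(sim$truth$tier == "stringent")
  clean_idx <- which(sim$truth$tier %in% c("stringent", "lenient"))
  pool <- if (length(str_idx) >= config$n_duplicate_pairs) str_idx else clean_idx
  dup_src <- sample(pool, config$n_duplicate_pairs)
  for (k in seq_along(dup_src)) {
    i <- dup_src[k]
    src <- sim$sites[i, ]
    len <- src$end - src$pos + 1L
    jit <- function() as.integer(round(runif(1, -0.0125, 0.0125) * len))
    id <- sprintf("dupcall%03d", k)
    co <- list(chrom = src$chrom, pos = src$pos + jit(),
               end = src$end + jit())
    newlen <- co$end - co$pos + 1L
    ## the copy drops a few genotype calls so the original (more complete
    ## record) is the canonical representative
    gt <- sim$gt[i, ]
    gt[sample.int(length(gt), 2L)] <- NA_integer_
    sim <- appendSite(sim, id, co, src$svtype, newlen,
                      sim$true_cn[i, ], gt,
                      list(dhffc = sim$dhffc[i, ], dhbfc = sim$dhbfc[i, ]),
                      tier = "duplicate", af = sim$truth$af[i],
                      duplicate_of = src$site_id, block = NULL)
  }
  sim
}

appendSite <- function(sim, id, co, svtype, len, true_cn, gt, fold, tier,
                       af, duplicate_of = NA_character_, block = NULL) {
  resolved <- runif(1) < sim$config$single_base_fraction
  ciw <- if (resolved) c(NA_integer_, NA_integer_, NA_integer_, NA_integer_)
         else { j <- sample(5:50, 2L); c(-j[1], j[1], -j[2], j[2]) }
  sim$sites <- rbind(sim$sites, data.frame(
    site_id = id, chrom = co$chrom, pos = co$pos, end = co$end,
    svtype = svtype,
    svlen = if (svtype == "DEL") -len else len,
    cipos1 = ciw[1], cipos2 = ciw[2], ciend1 = ciw[3], ciend2 = ciw[4]))
  sim$gt <- rbind(sim$gt, gt)
  sim$true_cn <- rbind(sim$true_cn, true_cn)
  sim$dhffc <- rbind(sim$dhffc, fold$dhffc)
  sim$dhbfc <- rbind(sim$dhbfc, fold$dhbfc)
  sim$truth <- rbind(sim$truth, data.frame(
    site_id = id, tier = tier, duplicate_of = duplicate_of, af = af))
  if (!is.null(block)) sim$blocks[[id]] <- block
  sim
}

## Truth tier of a freshly generated biallelic site: stringent iff the
## realized fold-coverage groups of the reported genotypes are fully ordered
## and non-overlapping (and the relevant carrier minima are non-zero),
## mirroring what genotype/depth concordance means by construction.
truthTier <- function(svtype, gt, fold) {
  rng <- function(g) {
    v <- fold[!is.na(gt) & gt == g]
    if (!length(v)) NULL else range(v)
  }
  r0 <- rng(0L); r1 <- rng(1L); r2 <- rng(2L)
  ok <- TRUE
  if (svtype == "DEL") {
    if (!is.null(r0) && !is.null(r1)) ok <- ok && r1[2] < r0[1]
    if (!is.null(r1) && !is.null(r2)) ok <- ok && r2[2] < r1[1]
    if (!is.null(r1)) ok <- ok && r1[1] != 0
  } else {
    if (!is.null(r0) && !is.null(r1)) ok <- ok && r1[1] > r0[2]
    if (!is.null(r1) && !is.null(r2)) ok <- ok && r2[1] > r1[2]
    if (!is.null(r1)) ok <- ok && r1[1] != 0
    if (!is.null(r2)) ok <- ok && r2[1] != 0
  }
  if (ok) "stringent" else "lenient"
}

#' Simulate a complete synthetic SV cohort
#'
#' Runs the full generator: pedigree, biallelic DEL/DUP sites with
#' genotype-conditional fold-coverage, multi-allelic loci, artifact injection
#' ([injectArtifacts]), linked SNPs, and synthetic gene models. Deterministic
#' for a fixed config (including its seed).
#'
#' @param config a [simulationConfig].
#' @return list with elements `cohort` ([SVCohort]), `truth` (per-site truth
#'   table: `site_id`, `tier` in stringent/lenient/spurious/duplicate/mcnv,
#'   `duplicate_of`, `af`), `true_gt` (true dosage matrix), `snps`
#'   ([GenotypeMatrix]), `pedigree`, `genes` (synthetic gene models in
#'   [readGeneModels] layout), and `blocks` (per-site haplotype blocks).
#' @export
simulateSVCohort <- function(config = simulationConfig()) {
  set.seed(config$seed)
  pedigree <- generatePedigree(config, seed = NULL)
  ns <- length(pedigree$samples)
  sim <- list(config = config, pedigree = pedigree,
              sites = data.frame(), gt = NULL, true_cn = NULL,
              dhffc = NULL, dhbfc = NULL,
              truth = data.frame(), blocks = list(),
              state = list(chrom_i = 1L, cursor = 0L))
  ## biallelic clean sites
  n_bi <- config$n_del + config$n_dup
  for (k in seq_len(n_bi)) {
    svtype <- if (k <= config$n_del) "DEL" else "DUP"
    seg <- segregatingSite(pedigree, config)
    true_cn <- if (svtype == "DEL") 2L - seg$true_dosage else
      2L + seg$true_dosage
    fold <- simulateFoldCoverage(true_cn, svtype, config)
    gt <- corruptGenotypes(seg$true_dosage, config$genotyping_error_rate)
    len <- drawLength()
    co <- newSiteCoords(sim$state, len); sim$state <- co$state
    id <- sprintf("%s%04d", tolower(svtype), k)
    field <- if (svtype == "DEL") fold$dhffc else fold$dhbfc
    sim <- appendSite(sim, id, co, svtype, len, true_cn, gt, fold,
                      tier = truthTier(svtype, gt, field), af = seg$af,
                      block = list(site_id = id, chrom = co$chrom,
                                   pos = co$pos, end = co$end,
                                   founder_haps = seg$founder_haps,
                                   transmission = seg$transmission))
  }
  ## multi-allelic loci: haploid CNs on founder haplotypes, naive biallelic
  ## reported genotypes (a haplotype with CN > 2 reads as an alt allele),
  ## reproducing the mis-genotyping of multi-allelic loci by biallelic callers
  for (k in seq_len(config$n_mcnv)) {
    repeat {
      hap <- sample(config$mcnv_allele_cns, 2L * length(pedigree$founders),
                    replace = TRUE, prob = config$mcnv_allele_probs)
      trans <- drawTransmission(nrow(pedigree$trios))
      cn <- sumHaplotypes(hap, pedigree, trans)
      if (length(unique(cn)) > 3L) break
    }
    hapmat_alt <- as.integer(hap > 2L)
    gt <- sumHaplotypes(hapmat_alt, pedigree, trans)
    fold <- simulateFoldCoverage(cn, "MCNV", config)
    len <- drawLength()
    co <- newSiteCoords(sim$state, len); sim$state <- co$state
    id <- sprintf("mcnv%03d", k)
    ## reported as DUP: biallelic callers see multi-allelic loci as
    ## duplications; the mCNV tier is assigned downstream from depth modes
    sim <- appendSite(sim, id, co, "DUP", len, cn,
                      corruptGenotypes(gt, config$genotyping_error_rate),
                      fold, tier = "mcnv", af = mean(hapmat_alt),
                      block = NULL)
  }
  sim <- injectArtifacts(sim, config)
  rownames(sim$gt) <- sim$sites$site_id
  rownames(sim$true_cn) <- sim$sites$site_id
  colnames(sim$gt) <- pedigree$samples
  cohort <- SVCohort(sim$sites, sim$gt, sim$dhffc, sim$dhbfc,
                     samples = pedigree$samples)
  ## linked SNPs for biallelic clean sites
  snp_parts <- list()
  for (id in sim$truth$site_id[sim$truth$tier %in% c("stringent", "lenient")]) {
    blk <- sim$blocks[[id]]
    if (is.null(blk)) next
    snp_parts[[id]] <- suppressWarnings(
      simulateLinkedSnps(blk, config$target_r2_levels,
                         n_snp = config$snp_per_cnv, pedigree = pedigree,
                         window = config$ld_window))
  }
  snps <- if (length(snp_parts)) {
    GenotypeMatrix(do.call(rbind, lapply(snp_parts, dosages)),
                   loci = do.call(rbind, c(lapply(snp_parts, loci),
                                           make.row.names = FALSE)),
                   samples = pedigree$samples)
  } else NULL
  genes <- simulateGeneModels(sim, config)
  truth <- sim$truth; rownames(truth) <- NULL
  true_gt <- matrix(NA_integer_, nrow(sim$sites), ns,
                    dimnames = list(sim$sites$site_id, pedigree$samples))
  bi <- truth$tier %in% c("stringent", "lenient", "duplicate")
  true_gt[bi & sim$sites$svtype == "DEL", ] <-
    2L - sim$true_cn[bi & sim$sites$svtype == "DEL", , drop = FALSE]
  true_gt[bi & sim$sites$svtype == "DUP", ] <-
    sim$true_cn[bi & sim$sites$svtype == "DUP", , drop = FALSE] - 2L
  list(cohort = cohort, truth = truth, true_gt = true_gt,
       true_cn = sim$true_cn, snps = snps, pedigree = pedigree,
       genes = genes, blocks = sim$blocks, config = config)
}

## Synthetic gene models overlapping a fraction of clean sites, arranged to
## exercise all three disruption classes (gene inside a DUP; partial overlap).
simulateGeneModels <- function(sim, config) {
  clean <- which(sim$truth$tier %in% c("stringent", "lenient"))
  n_genes <- max(1L, as.integer(round(length(clean) * config$gene_fraction)))
  pick <- sample(clean, min(n_genes, length(clean)))
  chroms <- character(); gstarts <- integer(); gends <- integer()
  cds <- list(); gid <- character()
  for (k in seq_along(pick)) {
    s <- sim$sites[pick[k], ]
    id <- sprintf("gene%03d", k)
    inside <- s$svtype == "DUP" && k %% 2 == 0 && (s$end - s$pos) > 200L
    if (inside) {  # gene fully inside the DUP -> copy gain
      gstart <- s$pos + 10L
      gend <- max(gstart + 50L, s$end - 10L)
    } else {       # gene straddles the right breakpoint -> partial overlap
      gstart <- max(1L, s$end - 100L)
      gend <- s$end + 500L
    }
    glen <- gend - gstart + 1L
    e1 <- IRanges(gstart, gstart + max(10L, glen %/% 4L))
    e2 <- IRanges(gend - max(10L, glen %/% 4L), gend)
    chroms[k] <- s$chrom; gstarts[k] <- gstart; gends[k] <- gend
    cds[[k]] <- reduce(GRanges(s$chrom, c(e1, e2), strand = "+"))
    gid[k] <- id
  }
  genes <- GRanges(chroms, IRanges(gstarts, gends), strand = "+")
  genes$gene_id <- gid
  cdsl <- GenomicRanges::GRangesList(cds)
  names(cdsl) <- gid
  list(genes = genes, cds = cdsl)
}

#' Write a simulated cohort as a fixture file set
#'
#' Writes the exact formats the readers consume: `sv.vcf` (via [writeSVVcf]),
#' `pedigree.ped`, `snps.tsv`, `genes.gff3` and `truth.tsv`. With a fixed
#' config the VCF body is byte-identical across runs.
#'
#' @param sim result of [simulateSVCohort].
#' @param dir output directory (created if absent).
#' @return named character vector of the five paths, invisibly.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "sv.vcf"),
             ped = file.path(dir, "pedigree.ped"),
             snps = file.path(dir, "snps.tsv"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  if (is.null(sim$snps)) stop("simulation has no SNPs; nothing to write")
  writeSVVcf(sim$cohort, paths["vcf"])
  write.table(sim$pedigree$trios[c("offspring", "father", "mother")],
              paths["ped"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeGenotypeMatrix(sim$snps, paths["snps"])
  writeGff3(sim$genes, paths["genes"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

## minimal GFF3 emission of the gene/mRNA/CDS hierarchy readGeneModels expects
writeGff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_along(genes$genes)) {
    g <- genes$genes[i]
    gid <- g$gene_id
    chrom <- as.character(seqnames(g))
    lines <- c(lines,
      sprintf("%s\tsvcurate\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom,
              start(g), end(g), as.character(strand(g)), gid),
      sprintf("%s\tsvcurate\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chrom, start(g), end(g), as.character(strand(g)), gid, gid))
    ex <- genes$cds[[gid]]
    for (j in seq_along(ex)) {
      lines <- c(lines,
        sprintf("%s\tsvcurate\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s.t1",
                chrom, start(ex)[j], end(ex)[j], as.character(strand(g)),
                gid, j, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
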