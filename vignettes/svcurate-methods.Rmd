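---
title: "Depth-aware curation of structural-variant call sets: models and choices"
author: "svcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-aware curation of structural-variant call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`svcurate` assumes an SV call set produced by a reads-evidence caller
(split reads + discordant pairs) on a diploid cohort, annotated per sample
with read-depth fold-coverage: DHFFC, depth of the SV region relative to its
1-kb flanks, and DHBFC, relative to GC-matched regions. For a true CNV the
fold-coverage is informative about the underlying copy number independently
of the reads-based genotype: a deletion carrier at diploid CN 1 sequenced at
15X against a 30X background has fold-coverage 0.5; a duplication carrier at
CN 3 has 1.5. For biallelic sites this predicts up to three depth clusters
ordered by dosage — descending for deletions (0/0 > 0/1 > 1/1), ascending
for duplications. Sites violating that prediction are either spuriously
called (depth flat at ~1 across genotypes) or mis-genotyped.

The pipeline has three decision layers:

1. **Clean-set filters.** Per site, fold-coverage statistics are computed
   per genotype group over non-missing calls (DHFFC for deletions, DHBFC
   for duplications — the flank-normalised measure is more sensitive for
   depth loss, the GC-matched one for depth gain). Deletions must satisfy:
   ratio of 0/0 to 0/1 group means > 1.39, both means non-zero,
   max of 0/0 < 3, max of 0/1 < 1.3, min of 0/0 > 0.1. Duplications:
   pooled carrier mean (all 0/1 and 1/1 calls pooled, not a mean of group
   means) over the 0/0 mean strictly between 1.2 and 5, min of 0/0 > 0.44,
   min of 0/1 > 0.5. All thresholds are strict inequalities exactly as
   written in the function documentation. Before the depth rules, sites
   are dropped when they are non-CNV types, shorter than 50 bp (a 50-bp
   site is retained), monomorphic (all 0/0 or all 1/1) or uniformly
   heterozygous (a reference-assembly artefact signature). After them,
   same-type records with at least 95% reciprocal overlap collapse to the
   record with the most non-missing genotype calls (ties: smaller start,
   then smaller site id), with transitive clusters collapsing to one
   representative.

2. **Tiers.** Clean sites are STRINGENT when the genotype-group depth
   ranges are fully ordered and disjoint (deletions: max 0/1 < min 0/0 and
   max 1/1 < min 0/1, min 0/1 not 0; duplications: the ascending analogue
   with both carrier minima non-zero), else LENIENT. Duplications whose
   cohort-wide DHBFC distribution has more than three modes are re-labelled
   MCNV: more than two structural alleles segregating, which a biallelic
   genotyper cannot represent.

3. **Cohort QC.** Mendelian-error fractions over trios, site-frequency
   spectra, breakpoint-resolution tallies, CNV-SNP LD tagging and
   CDS-disruption classes, as described in the README.

## Decisions where the design was open

* **Stringent deletion clauses.** The source rule set states both
  "max 0/1 < min 0/0" and "max 0/0 < min 0/1", which cannot hold
  simultaneously when both groups are non-empty. We read the second clause
  as a typo for the 1/1-vs-0/1 comparison, giving a fully ordered
  three-group criterion consistent with the expected depth ordering
  1/1 < 0/1 < 0/0 and with the duplication rules, which are printed in the
  ordered form. The literal reading remains available via
  `stringentDeletionTest(..., strict_printed = TRUE)`.
* **Empty genotype groups** make their clauses vacuous rather than failing:
  rare variants frequently lack 1/1 carriers and a stringent set must be
  able to contain them. In the deletion depth rules, a site with 1/1 but no
  0/1 carriers uses the 1/1 group as the carrier group in the ratio and
  max rules, so homozygous-only sites remain filterable.
* **Rule "neither mean is 0"** is applied to the group means (not to
  individual values); individual zero values in the 0/1 group are caught at
  the stringent stage instead.
* **Size filter** applies to deletions and duplications symmetrically;
  `basicSiteFilters(size_del_only = TRUE)` restricts it to deletions for
  exact replication of removal counts from deletion-only accounting.
* **Distances.** CNV-SNP distance is measured to the nearest breakpoint;
  the 100-kb window boundary is inclusive; SNPs inside the CNV are never
  paired with it. SNP-SNP distance is the position difference.
* **Copy-gain containment** uses the gene body (start-end); a flag switches
  to the CDS span. Strand is ignored for all overlap tests (SVs are
  unstranded), but the fusion-candidate note requires the two genes at the
  duplication breakpoints to share a strand.
* **Missing genotypes.** Trios with any missing member are uninformative:
  excluded from the error numerator but kept in the fixed all-trios
  denominator; effective mode drops them from both. Per-genotype-group
  statistics and allele frequencies use non-missing calls only; sites with
  call rate below 50% are flagged.
* **mCNV sites are excluded from LD tagging by default** because their
  biallelic genotypes are untrustworthy by construction;
  `cnvSnpPairs(exclude_mcnv = FALSE)` restores them for the "how poorly are
  mCNVs tagged" analysis.

## Mode counting

The multi-allelic screen replaces by-eye QC-plot inspection with a
deterministic surrogate: count local maxima of a Gaussian KDE over the
cohort's DHBFC values, merging maxima closer than `min_peak_separation`
(default 0.2 fold units, i.e. modes are expected at multiples of half a
copy) and ignoring maxima below `min_peak_fraction` (default 5%) of the
tallest peak. The default bandwidth is Silverman's rule-of-thumb scaled by
0.5 **and capped at `min_peak_separation / 2`**. Both guards earn their
keep: Silverman's rule assumes a roughly unimodal target and over-smooths a
distribution whose support spans fold-coverage 1 to 6, merging genuine
modes (we observed a true five-mode multi-allelic locus reduced to three
modes without the cap), while with narrow bandwidths a single outlier
sample otherwise contributes its own local maximum and inflates the mode
count (three biallelic duplications were mislabelled multi-allelic without
the height floor). With both guards, the default simulation recovers every
injected multi-allelic locus with zero false positives across seeds, and
the false-MCNV rate on purely biallelic cohorts stays below 1%. Sites with
fewer than ten depth values return `NA` (undetermined) and keep their
biallelic tier. Screening applies to duplications; deletions can be opted
in (`mcnv_on_deletions`).

## What the generator emulates — and what it does not

`simulateSVCohort()` produces a cohort whose defaults state the conditions
the pipeline targets: 266 samples of which 127 are trio offspring (founders
= 139; parents are drawn from the founders with replacement, so half-sib
families arise, as in real cattle cohorts); deletion fold-coverage means
0.91 / 0.55 / 0.03 for 0/0, 0/1, 1/1 and duplication means 1 / 1.22 / 1.45;
fold-coverage noise as a normal with sd 0.06 censored at zero (the sources
report means but no dispersion; 0.06 was chosen once so that default runs
produce both stringent and clearly lenient sites, and is not tuned
further); a rare-skewed Beta(0.3, 2.5) allele-frequency distribution
truncated at 0.005 and conditioned on segregating in the finite cohort
(more than half of simulated sites have MAF < 0.05); multi-allelic loci
with haploid copy numbers {1, 4, 5, 6} on founder haplotypes, reported
through a deliberately naive biallelic rule (a haplotype with CN > 2 reads
as one alt allele) to reproduce the genotype/depth discordance such loci
show under biallelic genotyping; spurious sites with pedigree-consistent
genotypes but depth pinned at ~1; duplicate call pairs jittered by at most
±1.25% of length per endpoint — the cap that *guarantees* ≥ 95% reciprocal
overlap in the worst case ((1−0.025)/(1+0.025) ≈ 0.951), which a ±5% jitter
would not; and per CNV a configurable number of SNPs placed on the founder
haplotypes at target r² levels (default one perfect tag at r² = 1 and one
moderate at 0.6) within 100 kb of the breakpoints, transmitted along the
same haplotype as the CNV (single-locus blocks, no recombination).

It does **not** emulate: read-level artefacts (mapping-quality loss in
repeats, GC waves), breakpoint micro-homology, genuine genomic clustering
of SVs (sites are spaced 250 kb apart so LD blocks never interact),
recombination within a block, selection, or depth-dependent call-rate
effects. A green simulation test therefore establishes that the *decision
logic* is correct under the stated statistical model — not that the
thresholds are optimal for any particular real cohort.

## Numerical and statistical notes

* **r² estimators.** `pairwiseR2` is the composite measure: squared Pearson
  correlation of 0/1/2 dosages over pairwise-complete samples — the default
  of standard LD software on unphased genotypes. `haplotypeR2` is the
  classical D²/(p_A(1−p_A)p_B(1−p_B)) on phased haplotypes. These are
  different finite-sample estimators: writing genotypes as sums of the two
  haplotype indicators, the dosage covariance contains within-individual
  cross terms (hap 1 of locus A with hap 2 of locus B) that the haplotype
  estimator does not, so exact equality holds only under complete
  association (all cross-locus haplotype pairs concordant), e.g. at target
  r² = 1 — where the package tests assert agreement to 1e-9. At
  intermediate LD the two agree only to O(1/n); tests compare them there
  only within sampling tolerance.
* **Censoring at zero** (rather than re-drawing) for fold-coverage noise
  means homozygous deletions genuinely hit fold-coverage 0, which is what
  makes the "carrier minimum not 0" stringent clauses meaningful.
* **Half-up rounding** is used for reported percentages
  (`fractionPercent`), matching how headline fractions like 229/371 → 62%
  are conventionally printed; an epsilon guards against binary
  representation of values like 12.5.
* **Determinism.** Simulation, resampling and the pipeline are reproducible
  from a config seed; the VCF writer emits a byte-identical body for a
  fixed config, and fold-coverage values round-trip through VCF at four
  decimals.
* **Duplicate-collapse representative** choice (most non-missing calls,
  then smaller position, then lexicographic id) makes the collapse
  deterministic under permutation of input order.

## Limitations

Inversions and breakends are excluded from all analyses, not interpreted.
Genotype likelihoods are ignored; genotypes are taken as called. The
Mendelian metric treats every site as autosomal. mCNV sites receive no
integer copy-number genotypes — the tier label is the end of the road.
Haplotype-EM r², D′ and LD pruning are out of scope, as are eQTL mapping
and any use of alignment-level data.
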