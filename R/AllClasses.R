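#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- rowRanges rowRanges<- colData
#' @importFrom GenomicRanges GRanges GRangesList granges findOverlaps
#'   pintersect seqnames start end width strand
#' @importFrom IRanges IRanges reduce
#' @importFrom stats rnorm rbinom rbeta runif density bw.nrd0 median setNames
#'   aggregate cor var sd
#' @importFrom graphics hist
#' @importFrom utils read.table write.table head packageVersion
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "BND", "MCNV")

#' SVCohort: a cohort-level structural-variant call set
#'
#' An `SVCohort` holds one multi-sample SV call set: one row per SV site and
#' one column per sample, built on [SummarizedExperiment::RangedSummarizedExperiment].
#' The `rowRanges` carry site coordinates (1-based, inclusive; the range end is
#' the VCF `END`) together with `site_id`, `svtype`, `svlen` and breakpoint
#' confidence intervals (`cipos1`, `cipos2`, `ciend1`, `ciend2`; `NA` when the
#' caller reported none, meaning the breakpoint is single-base resolved).
#' Assays:
#' \describe{
#'   \item{GT}{integer alternative-allele dosage per sample: 0 (0/0), 1 (0/1),
#'     2 (1/1), `NA` (missing).}
#'   \item{DHFFC}{read-depth fold-change of the SV region relative to 1-kb
#'     flanking regions; `NA` when unannotated.}
#'   \item{DHBFC}{read-depth fold-change relative to GC-matched regions.}
#' }
#'
#' @aliases SVCohort-class
#' @export
setClass("SVCohort", contains = "RangedSummarizedExperiment")

setValidity("SVCohort", function(object) {
  msg <- character()
  need <- c("GT", "DHFFC", "DHBFC")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  rd <- rowData(object)
  for (col in c("site_id", "svtype", "svlen"))
    if (!col %in% names(rd)) msg <- c(msg, paste("rowData lacks", col))
  # raw svtype tags outside SV_TYPES are retained (excluded later by the
  # cascade); they must merely be present
  if ("svtype" %in% names(rd) && anyNA(rd$svtype))
    msg <- c(msg, "svtype may not be NA")
  if ("site_id" %in% names(rd) && anyDuplicated(rd$site_id))
    msg <- c(msg, "site_id values must be unique")
  if ("GT" %in% names(assays(object))) {
    gt <- assay(object, "GT")
    if (!all(gt[!is.na(gt)] %in% 0:2))
      msg <- c(msg, "GT dosages must be 0, 1, 2 or NA")
  }
  if ("svtype" %in% names(rd) && nrow(object) > 0L) {
    cnv <- rd$svtype %in% c("DEL", "DUP", "MCNV")
    bad <- cnv & (end(rowRanges(object)) < start(rowRanges(object)))
    if (any(bad)) msg <- c(msg, "end < pos for a DEL/DUP record")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SVCohort from site and per-sample data
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`, `end`,
#'   `svtype`, `svlen` and optionally `cipos1`, `cipos2`, `ciend1`, `ciend2`.
#' @param gt integer matrix of allele dosages (sites x samples; NA = missing).
#' @param dhffc,dhbfc numeric matrices matching `gt` (NA = unannotated).
#' @param samples character vector of sample identifiers (column order).
#' @return An [SVCohort] object.
#' @export
SVCohort <- function(sites, gt, dhffc = NULL, dhbfc = NULL, samples = colnames(gt)) {
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  if (is.null(samples)) stop("sample identifiers are required")
  gt <- matrix(as.integer(gt), nrow = n, ncol = length(samples),
               dimnames = list(sites$site_id, samples))
  blank <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, nrow = n, ncol = length(samples))
    matrix(as.numeric(m), nrow = n, ncol = length(samples),
           dimnames = list(sites$site_id, samples))
  }
  for (col in c("cipos1", "cipos2", "ciend1", "ciend2"))
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_integer_, n)
  gr <- GRanges(sites$chrom,
                IRanges(sites$pos, pmax(sites$pos, sites$end)))
  names(gr) <- sites$site_id
  mcols(gr) <- DataFrame(site_id = sites$site_id,
                         svtype = as.character(sites$svtype),
                         svlen = as.integer(sites$svlen),
                         cipos1 = as.integer(sites$cipos1),
                         cipos2 = as.integer(sites$cipos2),
                         ciend1 = as.integer(sites$ciend1),
                         ciend2 = as.integer(sites$ciend2))
  se <- SummarizedExperiment(
    assays = SimpleList(GT = gt, DHFFC = blank(dhffc), DHBFC = blank(dhbfc)),
    rowRanges = gr)
  new("SVCohort", se)
}

#' @describeIn SVCohort site identifiers
#' @param x,object an `SVCohort`
#' @export
siteIDs <- function(x) rowData(x)$site_id

#' @describeIn SVCohort SV type per site (DEL/DUP/INV/BND/MCNV)
#' @export
svType <- function(x) rowData(x)$svtype

#' @describeIn SVCohort SV length in bp (absolute value as used by size filters)
#' @export
svLen <- function(x) abs(rowData(x)$svlen)

#' @describeIn SVCohort integer dosage matrix (0/1/2/NA)
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn SVCohort DHFFC matrix
#' @export
dhffc <- function(x) assay(x, "DHFFC")

#' @describeIn SVCohort DHBFC matrix
#' @export
dhbfc <- function(x) assay(x, "DHBFC")

setMethod("show", "SVCohort", function(object) {
  cat("SVCohort with", nrow(object), "sites x", ncol(object), "samples\n")
  tab <- table(factor(svType(object), levels = SV_TYPES))
  cat("  svtype:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if ("tier" %in% names(rowData(object))) {
    tt <- table(rowData(object)$tier)
    cat("  tiers: ", paste(names(tt), tt, sep = "=", collapse = " "), "\n")
  }
  invisible(NULL)
})

#' GenotypeMatrix: dosage genotypes for SNP/CNV loci
#'
#' Holds an integer dosage matrix (loci x samples, values 0/1/2/NA) plus locus
#' annotation (`locus_id`, `chrom`, `pos`, `is_cnv`). Used as the substrate of
#' the LD-tagging analyses.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
         representation(dosage = "matrix", loci = "data.frame",
                        samples = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@dosage) != nrow(object@loci))
    msg <- c(msg, "dosage rows must match loci")
  if (ncol(object@dosage) != length(object@samples))
    msg <- c(msg, "dosage columns must match samples")
  need <- c("locus_id", "chrom", "pos", "is_cnv")
  if (!all(need %in% names(object@loci)))
    msg <- c(msg, paste("loci must have columns", paste(need, collapse = ", ")))
  d <- object@dosage
  if (!all(d[!is.na(d)] %in% 0:2)) msg <- c(msg, "dosages must be 0/1/2/NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#' @param dosage integer matrix loci x samples (0/1/2/NA)
#' @param loci data.frame with locus_id, chrom, pos, is_cnv
#' @param samples character sample ids
#' @return A [GenotypeMatrix] object.
#' @export
GenotypeMatrix <- function(dosage, loci, samples = colnames(dosage)) {
  loci <- as.data.frame(loci)
  dosage <- matrix(as.integer(dosage), nrow = nrow(loci),
                   dimnames = list(loci$locus_id, samples))
  new("GenotypeMatrix", dosage = dosage, loci = loci,
      samples = as.character(samples))
}

#' @describeIn GenotypeMatrix dosage matrix accessor
#' @param x,object a `GenotypeMatrix`
#' @export
dosages <- function(x) x@dosage

#' @describeIn GenotypeMatrix locus annotation accessor
#' @export
loci <- function(x) x@loci

#' @describeIn GenotypeMatrix sample identifiers
#' @export
sampleIDs <- function(x) x@samples

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix with", nrow(object@loci), "loci x",
      length(object@samples), "samples (",
      sum(object@loci$is_cnv), "CNV,", sum(!object@loci$is_cnv), "SNP )\n")
  invisible(NULL)
})
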