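## Coding-sequence disruption classes:
##   PLOF                   deletion overlapping >= 1 bp of CDS
##   COPY_GAIN              duplication containing an entire gene body
##   INTRAGENIC_EXONIC_DUP  duplication overlapping CDS without containing
##                          the gene
## UTR/intron-only overlap does not qualify; strand is ignored (SVs are
## unstranded). A duplication spanning one gene entirely and part of another
## yields one call per gene with the appropriate class.

#' Classify SV-gene overlaps into disruption classes
#'
#' @param cohort an [SVCohort] (typically the clean call set; only DEL/DUP
#'   sites can produce calls).
#' @param genes gene models from [readGeneModels] (list with `genes` GRanges
#'   and `cds` GRangesList).
#' @param copy_gain_on_cds use the CDS span instead of the gene body for the
#'   copy-gain containment check.
#' @return data.frame of disruption calls: `site_id`, `gene_id`, `class`,
#'   `overlap_bp` (CDS overlap for PLOF/INTRAGENIC_EXONIC_DUP, contained gene
#'   length for COPY_GAIN), plus `fusion_candidate` — TRUE for duplications
#'   whose two breakpoints fall inside two distinct same-strand genes (a
#'   tandem arrangement can then produce a fusion transcript).
#' @export
classifyGeneOverlap <- function(cohort, genes, copy_gain_on_cds = FALSE) {
  gr <- rowRanges(cohort)
  types <- svType(cohort)
  gb <- genes$genes
  span <- if (copy_gain_on_cds) {
    unlist(range(genes$cds))[gb$gene_id]
  } else gb
  hits <- findOverlaps(gr, gb, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  rows <- list()
  for (k in seq_along(qi)) {
    i <- qi[k]; j <- si[k]
    if (!types[i] %in% c("DEL", "DUP")) next
    gid <- gb$gene_id[j]
    cds <- genes$cds[[gid]]
    cds_ov <- sum(width(GenomicRanges::intersect(
      GenomicRanges::granges(gr[i]), GenomicRanges::granges(cds),
      ignore.strand = TRUE)))  # SVs are unstranded
    contains <- start(gr)[i] <= start(span)[j] && end(gr)[i] >= end(span)[j]
    if (types[i] == "DEL") {
      if (cds_ov > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = siteIDs(cohort)[i], gene_id = gid, class = "PLOF",
          overlap_bp = cds_ov)
    } else {
      if (contains) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = siteIDs(cohort)[i], gene_id = gid, class = "COPY_GAIN",
          overlap_bp = end(span)[j] - start(span)[j] + 1L)
      } else if (cds_ov > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = siteIDs(cohort)[i], gene_id = gid,
          class = "INTRAGENIC_EXONIC_DUP", overlap_bp = cds_ov)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), gene_id = character(),
                      class = character(), overlap_bp = integer())
  ## fusion-candidate note: DUP breakpoints inside two distinct same-strand
  ## genes (no transcript model is constructed)
  out$fusion_candidate <- logical(nrow(out))
  for (i in which(types == "DUP")) {
    at_start <- gb$gene_id[start(gb) <= start(gr)[i] & end(gb) >= start(gr)[i]]
    at_end <- gb$gene_id[start(gb) <= end(gr)[i] & end(gb) >= end(gr)[i]]
    if (length(at_start) && length(at_end)) {
      cross <- expand.grid(a = at_start, b = at_end,
                           stringsAsFactors = FALSE)
      cross <- cross[cross$a != cross$b, , drop = FALSE]
      same_strand <- vapply(seq_len(nrow(cross)), function(r) {
        sa <- as.character(strand(gb))[match(cross$a[r], gb$gene_id)]
        sb <- as.character(strand(gb))[match(cross$b[r], gb$gene_id)]
        sa == sb
      }, logical(1))
      if (any(same_strand)) {
        sel <- out$site_id == siteIDs(cohort)[i]
        out$fusion_candidate[sel] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-sample disruption burden
#'
#' A sample is burdened by a disruption call when it carries the underlying
#' SV (genotype 0/1 or 1/1). Counts are per class per sample; the cohort mean
#' per class mirrors the per-individual burden summaries such catalogues
#' report.
#'
#' @param calls data.frame from [classifyGeneOverlap].
#' @param cohort the [SVCohort] the calls came from.
#' @return list with `per_sample` (data.frame: sample, class, count) and
#'   `mean` (named vector of cohort means per class).
#' @export
perSampleBurden <- function(calls, cohort) {
  gt <- genotypes(cohort)
  classes <- c("PLOF", "COPY_GAIN", "INTRAGENIC_EXONIC_DUP")
  per <- do.call(rbind, lapply(classes, function(cl) {
    sites <- calls$site_id[calls$class == cl]
    cnt <- if (!length(sites)) {
      rep(0L, ncol(gt))
    } else {
      idx <- match(sites, siteIDs(cohort))  # one row per call (site x gene)
      carried <- !is.na(gt[idx, , drop = FALSE]) & gt[idx, , drop = FALSE] > 0L
      colSums(carried)
    }
    data.frame(sample = colnames(gt), class = cl, count = cnt)
  }))
  rownames(per) <- NULL
  list(per_sample = per,
       mean = vapply(split(per$count, per$class), mean, numeric(1)))
}

#' Distinct genes affected per disruption class
#'
#' @param calls data.frame from [classifyGeneOverlap].
#' @return list with `by_class` (named vector of distinct gene counts) and
#'   `total` distinct genes (a gene hit by several classes counts once).
#' @export
affectedGeneSummary <- function(calls) {
  classes <- c("PLOF", "COPY_GAIN", "INTRAGENIC_EXONIC_DUP")
  by_class <- vapply(classes, function(cl)
    length(unique(calls$gene_id[calls$class == cl])), integer(1))
  list(by_class = by_class, total = length(unique(calls$gene_id)))
}
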