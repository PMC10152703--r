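## I/O between standard file formats and the in-memory domain objects.
## All in-memory coordinates are 1-based inclusive; VCF END is taken as
## 1-based inclusive and BED is converted from 0-based half-open at read time.

GT_TO_DOSAGE <- c("0/0" = 0L, "0|0" = 0L,
                  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
                  "1/1" = 2L, "1|1" = 2L,
                  "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_,
                  "./1" = NA_integer_, "1/." = NA_integer_,
                  "./0" = NA_integer_, "0/." = NA_integer_)

DOSAGE_TO_GT <- c("0/0", "0/1", "1/1")

#' Read a multi-sample SV VCF into an SVCohort
#'
#' Reads a duphold-style SV VCF (INFO: SVTYPE, END, SVLEN, CIPOS, CIEND;
#' FORMAT: GT plus optional per-sample DHFFC/DHBFC). Every data line yields one
#' site; sample order is preserved; depth fields absent from a record stay
#' `NA` (never zero). Records with SV types outside DEL/DUP/INV/BND/MCNV are
#' retained with the raw tag so the filter cascade can exclude them
#' explicitly.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return An [SVCohort].
#' @export
readSVVcf <- function(path) {
  checkVcfShape(path)
  vcf <- VariantAnnotation::readVcf(path)
  inf <- VariantAnnotation::info(vcf)
  gr <- rowRanges(vcf)
  n <- length(gr)
  svtype <- as.character(inf$SVTYPE)
  if (is.null(svtype) || !length(svtype)) svtype <- rep(NA_character_, n)
  svtype[is.na(svtype)] <- "BND"
  pos <- start(gr)
  endpos <- if ("END" %in% names(inf)) as.integer(inf$END) else rep(NA_integer_, n)
  endpos[is.na(endpos)] <- pos[is.na(endpos)]
  svlen <- if ("SVLEN" %in% names(inf)) as.integer(inf$SVLEN) else rep(NA_integer_, n)
  miss <- is.na(svlen) & svtype %in% c("DEL", "DUP", "MCNV")
  svlen[miss] <- (endpos - pos + 1L)[miss]
  ci <- function(tag, slot) {
    if (!tag %in% names(inf)) return(rep(NA_integer_, n))
    vapply(inf[[tag]], function(v) {
      if (length(v) < slot || is.na(v[slot])) NA_integer_ else as.integer(v[slot])
    }, integer(1))
  }
  ids <- rownames(vcf)
  if (is.null(ids)) ids <- paste0("site", seq_len(n))
  gts <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gts)) stop("VCF has no GT FORMAT field")
  unknown <- setdiff(unique(as.vector(gts)), names(GT_TO_DOSAGE))
  if (length(unknown))
    stop("non-biallelic or unsupported GT string(s): ",
         paste(unknown, collapse = ", "),
         " (multi-allelic loci must be encoded biallelically; ",
         "mCNV status is assigned from depth downstream)")
  gt <- matrix(GT_TO_DOSAGE[as.vector(gts)], nrow = n, ncol = ncol(gts),
               dimnames = dimnames(gts))
  depth <- function(tag) {
    m <- VariantAnnotation::geno(vcf)[[tag]]
    if (is.null(m)) m <- matrix(NA_real_, n, ncol(gt), dimnames = dimnames(gt))
    storage.mode(m) <- "double"
    m
  }
  sites <- data.frame(site_id = ids, chrom = as.character(seqnames(gr)),
                      pos = pos, end = endpos, svtype = svtype, svlen = svlen,
                      cipos1 = ci("CIPOS", 1L), cipos2 = ci("CIPOS", 2L),
                      ciend1 = ci("CIEND", 1L), ciend2 = ci("CIEND", 2L))
  SVCohort(sites, gt, depth("DHFFC"), depth("DHBFC"), samples = colnames(gts))
}

## Cheap structural pre-scan so malformed lines fail with a line number
## (readVcf's own errors do not point at the offending line).
checkVcfShape <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  nfield <- NA_integer_
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    lineno <- lineno + 1L
    if (startsWith(ln, "##")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (startsWith(ln, "#CHROM")) { nfield <- nf; next }
    if (is.na(nfield)) stop("VCF parse error at line ", lineno,
                            ": data before #CHROM header")
    if (nf != nfield)
      stop("VCF parse error at line ", lineno, ": expected ", nfield,
           " fields, found ", nf)
  }
  invisible(TRUE)
}

#' Write an SVCohort to a VCF file
#'
#' Emits a VCF 4.2 file with SVTYPE/END/SVLEN/CIPOS/CIEND INFO fields and
#' GT/DHFFC/DHBFC FORMAT fields. Depth values are written with four decimals,
#' so `readSVVcf(writeSVVcf(x))` preserves coordinates, genotypes and depths
#' to that precision. Call-set tiers, when supplied, are written as a `TIER`
#' INFO tag.
#'
#' @param cohort an [SVCohort].
#' @param path output path.
#' @param labels optional tier labels: a data.frame with columns `site_id` and
#'   `tier` (as returned by [classifyCleanCallset]) or a character vector
#'   named by site id.
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(cohort, path, labels = NULL) {
  tiers <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      tiers <- setNames(as.character(labels$tier), labels$site_id)
    } else tiers <- labels
  }
  samples <- colnames(cohort)
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Call-set tier assigned by svcurate\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DHFFC,Number=1,Type=Float,Description=\"Depth fold-change vs 1-kb flanking regions\">",
    "##FORMAT=<ID=DHBFC,Number=1,Type=Float,Description=\"Depth fold-change vs GC-matched regions\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- hdr
  if (nrow(cohort) > 0L) {
    rd <- rowData(cohort)
    gr <- rowRanges(cohort)
    gt <- genotypes(cohort); ff <- dhffc(cohort); bf <- dhbfc(cohort)
    fmtd <- function(x) ifelse(is.na(x), ".", sprintf("%.4f", x))
    gts <- matrix(ifelse(is.na(gt), "./.", DOSAGE_TO_GT[gt + 1L]), nrow = nrow(gt))
    body <- vapply(seq_len(nrow(cohort)), function(i) {
      info <- paste0("SVTYPE=", rd$svtype[i], ";END=", end(gr)[i],
                     ";SVLEN=", rd$svlen[i])
      if (!is.na(rd$cipos1[i]))
        info <- paste0(info, ";CIPOS=", rd$cipos1[i], ",", rd$cipos2[i])
      if (!is.na(rd$ciend1[i]))
        info <- paste0(info, ";CIEND=", rd$ciend1[i], ",", rd$ciend2[i])
      if (!is.null(tiers) && !is.na(tiers[rd$site_id[i]]))
        info <- paste0(info, ";TIER=", tiers[rd$site_id[i]])
      alt <- if (rd$svtype[i] %in% c("DEL", "DUP", "INV")) {
        paste0("<", rd$svtype[i], ">")
      } else if (rd$svtype[i] == "MCNV") "<CNV>" else "<BND>"
      calls <- paste(gts[i, ], fmtd(ff[i, ]), fmtd(bf[i, ]), sep = ":")
      paste(c(as.character(seqnames(gr)[i]), start(gr)[i], rd$site_id[i], "N",
              alt, ".", ".", info, "GT:DHFFC:DHBFC", calls), collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a trio pedigree file
#'
#' Whitespace- or tab-delimited rows in offspring-father-mother order ("0"
#' marks an unknown parent, PED convention). Rows with an unknown parent are
#' skipped with a message; duplicated offspring are an error.
#'
#' @param path pedigree file path.
#' @return data.frame with columns `offspring`, `father`, `mother`
#'   (one row per complete trio).
#' @export
readPedigree <- function(path) {
  empty <- data.frame(offspring = character(), father = character(),
                      mother = character())
  if (file.size(path) == 0) return(empty)
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    col.names = c("offspring", "father", "mother"))
  if (nrow(tab) == 0L) return(empty)
  incomplete <- tab$father == "0" | tab$mother == "0"
  if (any(incomplete))
    message("skipping ", sum(incomplete), " pedigree row(s) with unknown parents")
  tab <- tab[!incomplete, , drop = FALSE]
  if (anyDuplicated(tab$offspring))
    stop("duplicated offspring id(s): ",
         paste(unique(tab$offspring[duplicated(tab$offspring)]), collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' Check that pedigree samples exist in a cohort
#' @param trios data.frame from [readPedigree].
#' @param samples cohort sample identifiers.
#' @return `trios`, invisibly, or an error naming absent samples.
#' @export
validatePedigree <- function(trios, samples) {
  ids <- unique(unlist(trios[c("offspring", "father", "mother")]))
  absent <- setdiff(ids, samples)
  if (length(absent))
    stop("pedigree sample(s) absent from cohort: ", paste(absent, collapse = ", "))
  invisible(trios)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input must use the conventional gene/mRNA/CDS feature hierarchy; CDS
#' features are assigned to their gene through the Parent chain and a CDS
#' whose parent cannot be resolved to a gene is an error. BED12 blocks are
#' taken as the coding intervals of one gene per line. Overlapping coding
#' intervals of a gene are merged; all coordinates are returned 1-based
#' inclusive.
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed12"` (guessed from the extension by default).
#' @return list with `genes` (a [GenomicRanges::GRanges] of gene bodies with
#'   `gene_id`) and `cds` (a `GRangesList` of merged CDS intervals named by
#'   gene id).
#' @export
readGeneModels <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "bed12") {
    b <- rtracklayer::import(path, format = "BED")
    gene_id <- if (!is.null(b$name)) as.character(b$name) else
      paste0("gene", seq_along(b))
    cds <- lapply(seq_along(b), function(i) {
      blk <- b$blocks[[i]]
      if (is.null(blk) || !length(blk)) blk <- IRanges(1L, width(b)[i])
      reduce(GRanges(seqnames(b)[i],
                     IRanges(start(b)[i] + start(blk) - 1L,
                             start(b)[i] + end(blk) - 1L),
                     strand = strand(b)[i]))
    })
    genes <- GRanges(seqnames(b), IRanges(start(b), end(b)), strand = strand(b))
    genes$gene_id <- gene_id
    cds <- GenomicRanges::GRangesList(cds)
    names(cds) <- gene_id
    return(list(genes = genes, cds = cds))
  }
  g <- rtracklayer::import(path, format = "GFF3")
  type <- tolower(as.character(g$type))
  feat_id <- as.character(g$ID)
  is_gene <- type == "gene"
  is_tx <- type %in% c("mrna", "transcript")
  tx_parent <- setNames(
    vapply(g$Parent[is_tx], function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    feat_id[is_tx])
  gene_ids <- feat_id[is_gene]
  cds_idx <- which(type == "cds")
  cds_gene <- vapply(cds_idx, function(i) {
    p <- g$Parent[[i]]
    p <- if (length(p)) p[[1]] else NA_character_
    if (is.na(p)) stop("CDS without parent: feature ",
                       ifelse(is.na(feat_id[i]), i, feat_id[i]))
    if (p %in% gene_ids) return(p)
    if (p %in% names(tx_parent) && tx_parent[[p]] %in% gene_ids)
      return(tx_parent[[p]])
    stop("CDS parent not resolvable to a gene: feature ",
         ifelse(is.na(feat_id[i]), i, feat_id[i]), " (parent ", p, ")")
  }, character(1))
  genes <- g[is_gene]
  keep <- DataFrame(gene_id = gene_ids)
  mcols(genes) <- keep
  cds <- GenomicRanges::GRangesList(lapply(gene_ids, function(gid) {
    reduce(GenomicRanges::granges(g[cds_idx[cds_gene == gid]]))
  }))
  names(cds) <- gene_ids
  list(genes = genes, cds = cds)
}

#' Read a tab-separated dosage genotype matrix
#'
#' Expects columns `locus_id`, `chrom`, `pos`, `is_cnv` followed by one column
#' per sample holding dosages 0/1/2 (NA = missing).
#'
#' @param path TSV path.
#' @return A [GenotypeMatrix].
#' @export
readGenotypeMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  meta <- c("locus_id", "chrom", "pos", "is_cnv")
  if (!all(meta %in% names(tab)))
    stop("genotype matrix must have columns ", paste(meta, collapse = ", "))
  samples <- setdiff(names(tab), meta)
  GenotypeMatrix(as.matrix(tab[samples]),
                 loci = data.frame(locus_id = as.character(tab$locus_id),
                                   chrom = as.character(tab$chrom),
                                   pos = as.integer(tab$pos),
                                   is_cnv = as.logical(tab$is_cnv)),
                 samples = samples)
}

#' Write a GenotypeMatrix as TSV
#' @param gm a [GenotypeMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeMatrix <- function(gm, path) {
  tab <- cbind(loci(gm)[c("locus_id", "chrom", "pos", "is_cnv")],
               as.data.frame(dosages(gm), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
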