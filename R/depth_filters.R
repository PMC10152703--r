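## The six-step filter cascade from raw call set to clean call set.
##
## Deletions are filtered on DHFFC (depth vs 1-kb flanks), duplications on
## DHBFC (depth vs GC-matched regions). All rule thresholds are strict
## inequalities exactly as stated in their documentation.

FILTER_REASONS <- c("TYPE_EXCLUDED", "TOO_SMALL", "NON_POLYMORPHIC", "ALL_HET",
                    paste0("DEPTH_RULE_DEL_", letters[1:5]),
                    paste0("DEPTH_RULE_DUP_", letters[1:3]),
                    "DUPLICATE_CALL")

#' Per-genotype-group fold-coverage statistics for one site
#'
#' Statistics are computed over non-missing genotype calls only. Groups are
#' the three biallelic genotype classes 0/0, 0/1, 1/1 (dosages 0, 1, 2);
#' statistics are `NA` for empty groups.
#'
#' @param cohort an [SVCohort].
#' @param site site id or row index.
#' @param field `"dhffc"` or `"dhbfc"`.
#' @return object of class `gt_group_stats`: list of vectors `n`, `mean`,
#'   `min`, `max`, `sum` indexed by `g0`, `g1`, `g2`.
#' @export
groupStats <- function(cohort, site, field = c("dhffc", "dhbfc")) {
  field <- match.arg(field)
  i <- if (is.character(site)) match(site, siteIDs(cohort)) else site
  if (is.na(i)) stop("unknown site: ", site)
  gt <- genotypes(cohort)[i, ]
  vals <- if (field == "dhffc") dhffc(cohort)[i, ] else dhbfc(cohort)[i, ]
  bad <- !is.na(gt) & is.na(vals)
  if (any(bad))
    stop(field, " absent for non-missing call(s) at site ",
         siteIDs(cohort)[i], ": ", paste(names(gt)[bad], collapse = ", "))
  groupStatsFromValues(gt, vals)
}

groupStatsFromValues <- function(gt, vals) {
  one <- function(g) {
    v <- vals[!is.na(gt) & gt == g]
    if (!length(v)) {
      c(n = 0, mean = NA, min = NA, max = NA, sum = NA)
    } else c(n = length(v), mean = mean(v), min = min(v), max = max(v),
             sum = sum(v))
  }
  m <- vapply(0:2, one, numeric(5))
  colnames(m) <- c("g0", "g1", "g2")
  structure(list(n = m["n", ], mean = m["mean", ], min = m["min", ],
                 max = m["max", ], sum = m["sum", ]),
            class = "gt_group_stats")
}

#' Construct group statistics directly (for rule testing)
#' @param n,mean,min,max,sum numeric length-3 vectors (groups 0/0, 0/1, 1/1);
#'   `sum` defaults to `n * mean`.
#' @return a `gt_group_stats` object.
#' @export
makeGroupStats <- function(n, mean, min = mean, max = mean,
                           sum = n * mean) {
  lab <- c("g0", "g1", "g2")
  structure(list(n = setNames(n, lab), mean = setNames(mean, lab),
                 min = setNames(min, lab), max = setNames(max, lab),
                 sum = setNames(sum, lab)),
            class = "gt_group_stats")
}

#' Genotype-conditional depth rules for deletions
#'
#' A deletion site passes when, over its DHFFC group statistics: (a) the ratio
#' of mean fold-coverage in 0/0 carriers to that in 0/1 carriers exceeds 1.39,
#' (b) neither of those two means equals 0, (c) the highest 0/0 value is below
#' 3, (d) the highest 0/1 value is below 1.3, and (e) the lowest 0/0 value
#' exceeds 0.1. If the site has no 0/1 carriers but does have 1/1 carriers,
#' the 1/1 group stands in for the 0/1 group in rules (a), (b) and (d) (so
#' homozygous-only sites remain filterable); rules over an empty group pass
#' vacuously.
#'
#' @param stats a `gt_group_stats` object computed on DHFFC.
#' @return list with `pass` (logical) and `failing` (first failing rule id,
#'   e.g. `"DEPTH_RULE_DEL_a"`, or `NA`).
#' @export
deletionDepthFilter <- function(stats) {
  het <- if (stats$n["g1"] > 0) "g1" else if (stats$n["g2"] > 0) "g2" else NA
  fail <- function(rule) list(pass = FALSE,
                              failing = paste0("DEPTH_RULE_DEL_", rule))
  if (stats$n["g0"] > 0 && !is.na(het)) {
    ratio <- stats$mean["g0"] / stats$mean[het]
    if (!is.nan(ratio) && !(ratio > 1.39)) return(fail("a"))
    if (stats$mean["g0"] == 0 || stats$mean[het] == 0) return(fail("b"))
  }
  if (stats$n["g0"] > 0 && !(stats$max["g0"] < 3)) return(fail("c"))
  if (!is.na(het) && !(stats$max[het] < 1.3)) return(fail("d"))
  if (stats$n["g0"] > 0 && !(stats$min["g0"] > 0.1)) return(fail("e"))
  list(pass = TRUE, failing = NA_character_)
}

#' Genotype-conditional depth rules for duplications
#'
#' A duplication site passes when, over its DHBFC group statistics: (a) the
#' ratio of the pooled mean fold-coverage over all 0/1 and 1/1 carriers to the
#' 0/0 mean lies strictly between 1.2 and 5, (b) the lowest 0/0 value exceeds
#' 0.44, and (c) the lowest 0/1 value exceeds 0.5. The carrier mean pools all
#' 0/1 and 1/1 calls (not a mean of group means). Rules over empty groups
#' pass vacuously.
#'
#' @param stats a `gt_group_stats` object computed on DHBFC.
#' @return list with `pass` and `failing` (`"DEPTH_RULE_DUP_a"` ... or `NA`).
#' @export
duplicationDepthFilter <- function(stats) {
  fail <- function(rule) list(pass = FALSE,
                              failing = paste0("DEPTH_RULE_DUP_", rule))
  n_car <- stats$n["g1"] + stats$n["g2"]
  if (stats$n["g0"] > 0 && n_car > 0) {
    carrier_mean <- sum(stats$sum[c("g1", "g2")], na.rm = TRUE) / n_car
    ratio <- carrier_mean / stats$mean["g0"]
    if (is.nan(ratio) || !(ratio > 1.2 && ratio < 5)) return(fail("a"))
  }
  if (stats$n["g0"] > 0 && !(stats$min["g0"] > 0.44)) return(fail("b"))
  if (stats$n["g1"] > 0 && !(stats$min["g1"] > 0.5)) return(fail("c"))
  list(pass = TRUE, failing = NA_character_)
}

ledgerRow <- function(step, cohort, idx, reason) {
  if (!length(idx)) {
    return(data.frame(step = character(), site_id = character(),
                      svtype = character(), reason = character()))
  }
  data.frame(step = step, site_id = siteIDs(cohort)[idx],
             svtype = svType(cohort)[idx], reason = reason)
}

#' Basic site-level filters
#'
#' Removes, in order: sites with `|svlen|` below `min_size` (50 bp; sites of
#' exactly 50 bp are retained), sites that are not polymorphic (all non-missing
#' genotypes 0/0, or all 1/1 — a putative reference artefact), and sites where
#' every non-missing genotype is 0/1 (suggesting an assembly issue). Sites
#' with zero non-missing genotypes are removed as NON_POLYMORPHIC with a
#' warning. Input is expected to already be restricted to DEL/DUP.
#'
#' @param cohort an [SVCohort] of DEL/DUP sites.
#' @param min_size minimum size in bp (retained when `|svlen| >= min_size`).
#' @param size_del_only if `TRUE`, apply the size filter to deletions only.
#' @return list with `retained` ([SVCohort]) and `ledger` (removals
#'   data.frame: step, site_id, svtype, reason).
#' @export
basicSiteFilters <- function(cohort, min_size = 50L, size_del_only = FALSE) {
  ledger <- list()
  small <- svLen(cohort) < min_size
  if (size_del_only) small <- small & svType(cohort) == "DEL"
  ledger$size <- ledgerRow("size", cohort, which(small), "TOO_SMALL")
  cohort <- cohort[!small, ]
  gt <- genotypes(cohort)
  nn <- rowSums(!is.na(gt))
  all0 <- rowSums(gt == 0L, na.rm = TRUE) == nn
  all2 <- rowSums(gt == 2L, na.rm = TRUE) == nn
  none <- nn == 0L
  if (any(none))
    warning(sum(none), " site(s) with zero non-missing genotypes removed as ",
            "NON_POLYMORPHIC")
  nonpoly <- (all0 | all2 | none)
  ledger$polymorphic <- ledgerRow("polymorphic", cohort, which(nonpoly),
                                  "NON_POLYMORPHIC")
  cohort <- cohort[!nonpoly, ]
  gt <- genotypes(cohort)
  allhet <- rowSums(gt == 1L, na.rm = TRUE) == rowSums(!is.na(gt))
  ledger$allhet <- ledgerRow("all_het", cohort, which(allhet), "ALL_HET")
  cohort <- cohort[!allhet, ]
  list(retained = cohort, ledger = do.call(rbind, unname(ledger)))
}

overlapWidth <- function(ga, ia, gb, ib) {
  pmax(pmin(end(ga)[ia], end(gb)[ib]) - pmax(start(ga)[ia], start(gb)[ib]) + 1L,
       0L)
}

reciprocalOverlap <- function(gr, i, j) {
  ov <- overlapWidth(gr, i, gr, j)
  pmin(ov / width(gr)[i], ov / width(gr)[j])
}

#' Collapse redundant duplicate calls
#'
#' Same-type record pairs with reciprocal overlap at or above the threshold
#' are treated as one variant reported twice; transitive clusters collapse to
#' a single representative — the record with the most non-missing genotype
#' calls (ties: smaller start position, then lexicographically smaller site
#' id).
#'
#' @param cohort an [SVCohort].
#' @param min_reciprocal_overlap overlap threshold (both directions).
#' @return list with `retained` ([SVCohort]), `removed_ids`, and `ledger`.
#' @export
collapseDuplicateCalls <- function(cohort, min_reciprocal_overlap = 0.95) {
  gr <- rowRanges(cohort)
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same <- svType(cohort)[qi] == svType(cohort)[si]
  qi <- qi[same]; si <- si[same]
  if (length(qi)) {
    ro <- reciprocalOverlap(gr, qi, si)
    keep <- ro >= min_reciprocal_overlap
    qi <- qi[keep]; si <- si[keep]
  }
  removed <- integer()
  if (length(qi)) {
    ## union-find over duplicate pairs; one representative per cluster
    parent <- seq_len(nrow(cohort))
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in seq_along(qi)) {
      a <- find(qi[k]); b <- find(si[k])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(nrow(cohort)), find, integer(1))
    ncalls <- rowSums(!is.na(genotypes(cohort)))
    pos <- start(gr)
    for (r in unique(roots[duplicated(roots)])) {
      members <- which(roots == r)
      ord <- order(-ncalls[members], pos[members], siteIDs(cohort)[members])
      removed <- c(removed, members[ord][-1])
    }
  }
  list(retained = cohort[setdiff(seq_len(nrow(cohort)), removed), ],
       removed_ids = siteIDs(cohort)[removed],
       ledger = ledgerRow("duplicates", cohort, removed, "DUPLICATE_CALL"))
}

#' Run the full filter cascade
#'
#' Applies, in order: exclusion of non-CNV types (INV/BND and unknown tags),
#' [basicSiteFilters], the genotype-conditional depth rules
#' ([deletionDepthFilter] on DELs via DHFFC, [duplicationDepthFilter] on DUPs
#' via DHBFC), and [collapseDuplicateCalls]. The ledger records every removal
#' with its reason, and the per-step summary conserves counts
#' (input = retained + removed for every step and svtype).
#'
#' @param cohort raw [SVCohort] from [readSVVcf] or [simulateSVCohort].
#' @param min_size minimum SV size in bp.
#' @param min_reciprocal_overlap duplicate-collapse threshold.
#' @param size_del_only restrict the size filter to deletions.
#' @return list with `clean` ([SVCohort]), `ledger` (all removals), and
#'   `summary` (per step: input, removed, retained counts by svtype).
#' @export
runFilterCascade <- function(cohort, min_size = 50L,
                             min_reciprocal_overlap = 0.95,
                             size_del_only = FALSE) {
  steps <- list()
  summarize <- function(step, before, removed_ledger) {
    types <- unique(svType(before))
    do.call(rbind, lapply(types, function(tp) {
      inp <- sum(svType(before) == tp)
      rem <- sum(removed_ledger$svtype == tp)
      data.frame(step = step, svtype = tp, input = inp, removed = rem,
                 retained = inp - rem)
    }))
  }
  ## step 1: type exclusion
  cnv <- svType(cohort) %in% c("DEL", "DUP")
  led <- ledgerRow("type", cohort, which(!cnv), "TYPE_EXCLUDED")
  steps[[1]] <- list(ledger = led, summary = summarize("type", cohort, led))
  cohort <- cohort[cnv, ]
  ## steps 2-4: size / polymorphism / all-het
  before <- cohort
  bf <- basicSiteFilters(cohort, min_size = min_size,
                         size_del_only = size_del_only)
  steps[[2]] <- list(ledger = bf$ledger,
                     summary = summarize("basic", before, bf$ledger))
  cohort <- bf$retained
  ## step 5: depth rules
  before <- cohort
  gt <- genotypes(cohort); ff <- dhffc(cohort); bfm <- dhbfc(cohort)
  types <- svType(cohort)
  failing <- vapply(seq_len(nrow(cohort)), function(i) {
    vals <- if (types[i] == "DEL") ff[i, ] else bfm[i, ]
    bad <- !is.na(gt[i, ]) & is.na(vals)
    if (any(bad))
      stop(if (types[i] == "DEL") "dhffc" else "dhbfc",
           " absent for non-missing call(s) at site ", siteIDs(cohort)[i],
           ": ", paste(colnames(gt)[bad], collapse = ", "))
    st <- groupStatsFromValues(gt[i, ], vals)
    res <- if (types[i] == "DEL") deletionDepthFilter(st) else
      duplicationDepthFilter(st)
    if (res$pass) NA_character_ else res$failing
  }, character(1))
  led <- ledgerRow("depth", cohort, which(!is.na(failing)),
                   failing[!is.na(failing)])
  steps[[3]] <- list(ledger = led, summary = summarize("depth", before, led))
  cohort <- cohort[is.na(failing), ]
  ## step 6: duplicate collapsing
  before <- cohort
  dc <- collapseDuplicateCalls(cohort, min_reciprocal_overlap)
  steps[[4]] <- list(ledger = dc$ledger,
                     summary = summarize("duplicates", before, dc$ledger))
  cohort <- dc$retained
  ledger <- do.call(rbind, lapply(steps, `[[`, "ledger"))
  rownames(ledger) <- NULL
  summary <- do.call(rbind, lapply(steps, `[[`, "summary"))
  rownames(summary) <- NULL
  list(clean = cohort, ledger = ledger, summary = summary)
}

#' Match two call sets by reciprocal overlap
#'
#' Pairs same-type records whose overlap length is at least
#' `min_reciprocal_overlap` of both record lengths; each record is matched at
#' most once, greedily by descending reciprocal overlap.
#'
#' @param set_a,set_b [SVCohort] objects (or GRanges carrying an `svtype`
#'   metadata column).
#' @param min_reciprocal_overlap threshold applied to both directions.
#' @return list with `pairs` (data.frame: id_a, id_b, svtype, overlap) and
#'   `counts` (matched pairs per svtype).
#' @export
callsetReciprocalOverlap <- function(set_a, set_b,
                                     min_reciprocal_overlap = 0.95) {
  asGr <- function(x) {
    if (is(x, "SVCohort")) {
      gr <- rowRanges(x)
      gr$svtype <- svType(x); gr$site_id <- siteIDs(x)
      gr
    } else x
  }
  ga <- asGr(set_a); gb <- asGr(set_b)
  ## disjoint seqlevels between the two sets are a legitimate zero-match
  ## comparison, not a user error worth a seqinfo warning
  hits <- suppressWarnings(findOverlaps(ga, gb))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same <- ga$svtype[qi] == gb$svtype[si]
  qi <- qi[same]; si <- si[same]
  empty <- data.frame(id_a = character(), id_b = character(),
                      svtype = character(), overlap = numeric())
  if (!length(qi)) return(list(pairs = empty, counts = table(character())))
  ov <- overlapWidth(ga, qi, gb, si)
  ro <- pmin(ov / width(ga)[qi], ov / width(gb)[si])
  keep <- ro >= min_reciprocal_overlap
  qi <- qi[keep]; si <- si[keep]; ro <- ro[keep]
  ord <- order(-ro)
  used_a <- logical(length(ga)); used_b <- logical(length(gb))
  sel <- logical(length(ord))
  for (k in ord) {
    if (!used_a[qi[k]] && !used_b[si[k]]) {
      sel[k] <- TRUE; used_a[qi[k]] <- TRUE; used_b[si[k]] <- TRUE
    }
  }
  pairs <- data.frame(id_a = ga$site_id[qi[sel]], id_b = gb$site_id[si[sel]],
                      svtype = ga$svtype[qi[sel]], overlap = ro[sel])
  list(pairs = pairs, counts = table(pairs$svtype))
}
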