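#' Count reads per annotated element
#'
#' Each read is counted at most once, toward the element with the largest
#' overlap of its primary alignment; ties go to the leftmost element
#' (chromosome order, then start). Overlaps below `min_overlap` bp are
#' ignored; reads assigned to no element are tallied as unassigned.
#'
#' @param alignments an `mb_alignments` data.frame (primary flags required).
#' @param annotation TE annotation data.frame (chrom, start, end, id), sorted
#'   or not.
#' @param min_overlap minimum overlap (bp) between alignment and element.
#' @return list with `counts` (named integer vector over all annotation ids)
#'   and `unassigned` (count of primary alignments not assigned).
#' @export
count_reads_per_element <- function(alignments, annotation, min_overlap = 100L) {
  prim <- alignments[alignments$is_primary %in% TRUE, , drop = FALSE]
  counts <- stats::setNames(integer(nrow(annotation)), annotation$id)
  if (!nrow(prim))
    return(list(counts = counts, unassigned = 0L))
  if (!all(prim$target_id %in% annotation$chrom))
    stop("alignment references an unknown chromosome: ",
         paste(setdiff(prim$target_id, annotation$chrom), collapse = ", "))
  chrom_order <- unique(annotation$chrom)
  ann <- annotation[order(match(annotation$chrom, chrom_order), annotation$start), ,
                    drop = FALSE]
  q <- GenomicRanges::GRanges(prim$target_id,
                              IRanges::IRanges(prim$target_start + 1L,
                                               prim$target_end))
  s <- GenomicRanges::GRanges(ann$chrom,
                              IRanges::IRanges(ann$start + 1L, ann$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qh],
                                            IRanges::ranges(s)[sh]))
    keep <- w >= min_overlap
    qh <- qh[keep]; sh <- sh[keep]; w <- w[keep]
    if (length(qh)) {
      # per read: largest overlap, ties to the leftmost element (sorted order)
      ord <- order(qh, -w, sh)
      first <- !duplicated(qh[ord])
      pick <- sh[ord][first]
      tab <- table(ann$id[pick])
      counts[names(tab)] <- as.integer(tab)
    }
  }
  list(counts = counts, unassigned = nrow(prim) - sum(counts))
}

#' Normalised count per 100,000 sequenced reads
#'
#' @param count read count.
#' @param library_total total reads in the library.
#' @return `100000 * count / library_total`.
#' @export
normalize_cpm100k <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  1e5 * count / library_total
}

#' Differential eccDNA activity between treatment and control
#'
#' Per element, a 2x2 contingency table
#' \code{[[reads_treat, total_treat - reads_treat],
#'        [reads_ctrl, total_ctrl - reads_ctrl]]}
#' is tested with a two-sided Fisher exact test. Multiple-testing correction
#' (Benjamini-Hochberg by default, Bonferroni optionally) is computed over
#' elements exceeding `min_reads` combined reads. An element is significant
#' when the adjusted p-value is below `alpha`, the normalised treatment count
#' exceeds the control one, and the combined read count exceeds `min_reads`.
#'
#' @param counts_treat,counts_ctrl named integer vectors (same element set).
#' @param totals integer vector of length 2: library totals
#'   (treatment, control).
#' @param min_reads combined read threshold (elements at or below it are
#'   labelled low_count and excluded from correction).
#' @param alpha adjusted-significance level.
#' @param method "BH" or "bonferroni".
#' @return data.frame of class `ecc_peaks`, sorted by adjusted p then id:
#'   element_id, reads_treat, reads_ctrl, total_treat, total_ctrl,
#'   cpm100k_treat, cpm100k_ctrl, p_value, p_adj, status.
#' @export
call_differential <- function(counts_treat, counts_ctrl, totals,
                              min_reads = 10L, alpha = 0.01,
                              method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ids <- union(names(counts_treat), names(counts_ctrl))
  ct <- stats::setNames(rep(0L, length(ids)), ids)
  cc <- ct
  ct[names(counts_treat)] <- as.integer(counts_treat)
  cc[names(counts_ctrl)] <- as.integer(counts_ctrl)
  if (any(totals <= 0)) stop("library totals must be positive")
  if (any(ct < 0) || any(cc < 0)) stop("negative counts")
  if (any(ct > totals[1]) || any(cc > totals[2]))
    stop("element count exceeds library total")
  p <- vapply(seq_along(ids), function(i) {
    m <- matrix(c(ct[i], totals[1] - ct[i], cc[i], totals[2] - cc[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, numeric(1))
  tested <- (ct + cc) > min_reads
  p_adj <- rep(NA_real_, length(ids))
  p_adj[tested] <- stats::p.adjust(p[tested], method = method)
  cpm_t <- normalize_cpm100k(ct, totals[1])
  cpm_c <- normalize_cpm100k(cc, totals[2])
  status <- ifelse(!tested, "low_count",
                   ifelse(p_adj < alpha & cpm_t > cpm_c, "significant", "tested"))
  out <- data.frame(element_id = ids, reads_treat = unname(ct),
                    reads_ctrl = unname(cc), total_treat = totals[1],
                    total_ctrl = totals[2], cpm100k_treat = unname(cpm_t),
                    cpm100k_ctrl = unname(cpm_c), p_value = unname(p),
                    p_adj = unname(p_adj), status = unname(status),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$element_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ecc_peaks", "data.frame")
  out
}

#' @export
print.ecc_peaks <- function(x, ...) {
  cat(sprintf("eccDNA differential activity: %d elements, %d tested, %d significant\n",
              nrow(x), sum(x$status != "low_count"),
              sum(x$status == "significant")))
  NextMethod()
}

#' Per-element coverage depth track from eccDNA alignments
#'
#' Simple per-base depth of primary alignments across one element interval
#' (a coverage-profile analogue for plotting).
#'
#' @param alignments `mb_alignments` table.
#' @param annotation annotation data.frame.
#' @param element_id element to profile.
#' @return integer vector of depth per element base.
#' @export
element_depth <- function(alignments, annotation, element_id) {
  a <- annotation[annotation$id == element_id, ]
  if (!nrow(a)) stop("unknown element id")
  prim <- alignments[alignments$is_primary %in% TRUE &
                       alignments$target_id == a$chrom, , drop = FALSE]
  depth <- integer(a$end - a$start)
  for (i in seq_len(nrow(prim))) {
    s <- max(prim$target_start[i], a$start) - a$start
    e <- min(prim$target_end[i], a$end) - a$start
    if (e > s) depth[(s + 1L):e] <- depth[(s + 1L):e] + 1L
  }
  depth
}
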