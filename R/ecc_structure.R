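#' Decompose a rolling-circle concatemer read into monomers
#'
#' The element sequence is aligned against the read (read as target); tandem
#' hits define monomer copies. The monomer length is the median spacing
#' between successive hits of the same element segment; the read is tiled into
#' monomer windows from the first hit, and a window covered over
#' `min_monomer_frac` of its span counts as a full monomer. Internal window
#' boundaries are junction-supported when the alignment coverage gap across
#' the boundary is below `junction_tol` bp. The consensus is the per-column
#' majority base over full-monomer alignments projected onto element
#' coordinates (requires at least two full monomers).
#'
#' @param read read sequence (character scalar), >= 200 bp for meaningful
#'   decomposition.
#' @param element_seq element sequence in element orientation (non-empty).
#' @param read_id,element_id identifiers stored in the result.
#' @param params aligner parameters; the default lowers `min_aln_len` so short
#'   solo-LTR fragments are still anchored.
#' @param min_monomer_frac coverage fraction for a full monomer.
#' @param junction_tol maximum uncovered stretch (bp) across a supported
#'   junction.
#' @return An object of class `monomer_decomposition`: read_id, element_id,
#'   monomer_len, n_full_monomers, monomer_intervals (read-relative
#'   data.frame), junction_supported (logical), consensus (character, possibly
#'   empty), plus alignment detail used by the classifier (hits, element-level
#'   pileups and coverage).
#' @export
decompose_concatemer <- function(read, element_seq, read_id = "read",
                                 element_id = "element",
                                 params = aligner_params(min_aln_len = 30L,
                                                         min_chain_seeds = 2L),
                                 min_monomer_frac = 0.9, junction_tol = 50L) {
  element_seq <- as.character(element_seq)
  if (nchar(element_seq) == 0L) stop("element sequence is empty")
  read <- as.character(read)
  elen <- nchar(element_seq)
  empty <- structure(list(read_id = read_id, element_id = element_id,
                          monomer_len = NA_real_, n_full_monomers = 0L,
                          monomer_intervals = data.frame(start = integer(),
                                                         end = integer()),
                          junction_supported = logical(0), consensus = "",
                          hits = empty_alignments(), element_len = elen,
                          pile_full = NULL, pile_all = NULL,
                          cov_best = NULL, read_len = nchar(read),
                          read = read),
                     class = "monomer_decomposition")
  if (nchar(read) < 200L) return(empty)
  idx <- build_reference_index(stats::setNames(read, "read"), k = params$k)
  hits <- map_long_read(element_seq, idx, params, query_id = element_id)
  if (!nrow(hits)) return(empty)
  # use the majority strand only (RCA chimeras are not modelled)
  strand_w <- tapply(hits$target_end - hits$target_start, hits$strand, sum)
  strand <- names(which.max(strand_w))
  hits <- hits[hits$strand == strand, , drop = FALSE]

  # drop duplicate representations: with (near-)identical element LTRs the
  # same read segment can align both as the 5' and as the 3' LTR; keep only
  # the best hit when a hit's read interval is contained in a kept one
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    for (j in (i + 1L):nrow(hits)) {
      if (!keep[j]) next
      ov <- min(hits$target_end[i], hits$target_end[j]) -
        max(hits$target_start[i], hits$target_start[j])
      if (ov >= 0.8 * (hits$target_end[j] - hits$target_start[j]))
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]

  # monomer length: median spacing between hits of the same element segment
  ord <- order(hits$query_start, hits$target_start)
  hits <- hits[ord, , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(hits$query_start) > 50))
  spacings <- numeric(0)
  for (g in split(seq_len(nrow(hits)), grp)) {
    if (length(g) < 2) next
    # only pair hits of comparable span: short re-interpretations of an LTR
    # share the query start of a full monomer hit but are not monomer onsets
    span <- hits$target_end[g] - hits$target_start[g]
    g <- g[span >= 0.5 * max(span)]
    if (length(g) < 2) next
    # correct each spacing by the query-offset difference so terminal
    # partial copies (which start mid-segment) do not bias the period
    o2 <- g[order(hits$target_start[g])]
    spacings <- c(spacings, diff(hits$target_start[o2]) -
                    diff(hits$query_start[o2]))
  }
  monomer_len <- if (length(spacings)) {
    stats::median(spacings)
  } else if (nrow(hits) > 1) {
    # fewer than two full periods: successive hits are the same periodic
    # structure entered at different element offsets, so the period is the
    # target spacing corrected by the query offset difference
    ord2 <- order(hits$target_start)
    est <- diff(hits$target_start[ord2]) - diff(hits$query_start[ord2])
    est <- est[est >= 50]
    if (length(est)) stats::median(est) else
      max(hits$target_end - hits$target_start)
  } else max(hits$target_end - hits$target_start)

  # guard against period doubling: when the two element LTRs are near
  # identical, alternating 5'/3' interpretations of the same circle segment
  # can place successive copies in different query groups; cross-check with
  # the reference-free k-mer periodicity of the read itself
  if (length(spacings) && is.finite(monomer_len) && monomer_len > 0) {
    p0 <- estimate_circle_period(read, k = params$k,
                                 max_period = ceiling(monomer_len * 1.25))
    if (!is.na(p0) && monomer_len > 1.7 * p0) {
      m <- round(monomer_len / p0)
      if (m >= 2 && abs(monomer_len / m - p0) <= 0.1 * p0)
        monomer_len <- monomer_len / m
    }
  }

  # read coverage by hits, windows of one monomer from the first hit
  rl <- nchar(read)
  cov <- logical(rl)
  for (i in seq_len(nrow(hits)))
    cov[(hits$target_start[i] + 1L):hits$target_end[i]] <- TRUE
  t0 <- min(hits$target_start)
  n_win <- max(0L, floor((rl - t0) / monomer_len))
  win_start <- t0 + round(monomer_len * (seq_len(n_win) - 1L))
  win_end <- t0 + round(monomer_len * seq_len(n_win))
  full <- logical(n_win)
  for (w in seq_len(n_win))
    full[w] <- mean(cov[(win_start[w] + 1L):min(win_end[w], rl)]) >= min_monomer_frac
  monomer_intervals <- data.frame(start = win_start[full], end = pmin(win_end[full], rl))

  # junction support: boundary between consecutive windows is supported when
  # it does not fall in an uncovered run longer than junction_tol
  junction <- logical(max(0L, n_win - 1L))
  if (n_win > 1) {
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- !r$values & r$lengths > junction_tol
    for (b in seq_len(n_win - 1L)) {
      pos <- win_end[b]
      inbad <- any(bad & starts <= pos & ends >= pos)
      junction[b] <- !inbad
    }
  }

  # project hits onto element coordinates
  pile_rows <- lapply(seq_len(nrow(hits)), function(i)
    orient_for_pileup(hits[i, ], read, on = "query"))
  pile_all <- mb_pileup(elen,
                        vapply(pile_rows, `[[`, numeric(1), "tstart"),
                        vapply(pile_rows, `[[`, numeric(1), "qstart"),
                        vapply(pile_rows, `[[`, character(1), "cigar"),
                        vapply(pile_rows, `[[`, character(1), "qseq"))
  # full-monomer hits: hits whose read interval lies mostly inside a full window
  in_full <- vapply(seq_len(nrow(hits)), function(i) {
    if (!nrow(monomer_intervals)) return(FALSE)
    ov <- pmin(hits$target_end[i], monomer_intervals$end) -
      pmax(hits$target_start[i], monomer_intervals$start)
    hlen <- hits$target_end[i] - hits$target_start[i]
    wlen <- monomer_intervals$end - monomer_intervals$start
    any(ov >= 0.5 * pmin(hlen, wlen))
  }, logical(1))
  pile_full <- if (any(in_full))
    mb_pileup(elen,
              vapply(pile_rows[in_full], `[[`, numeric(1), "tstart"),
              vapply(pile_rows[in_full], `[[`, numeric(1), "qstart"),
              vapply(pile_rows[in_full], `[[`, character(1), "cigar"),
              vapply(pile_rows[in_full], `[[`, character(1), "qseq")) else NULL
  best <- which.max(hits$score)
  cov_best <- integer(elen)
  cov_best[(hits$query_start[best] + 1L):hits$query_end[best]] <- 1L

  n_full <- sum(full)
  consensus <- ""
  if (n_full >= 2 && !is.null(pile_full)) {
    bases <- c("A", "C", "G", "T")
    top <- apply(pile_full[1:4, , drop = FALSE], 2, which.max)
    cnt <- pile_full[cbind(top, seq_len(elen))]
    depth <- colSums(pile_full[c(1:4, 6), , drop = FALSE])
    keep <- depth > 0 & cnt > pile_full[6, ]   # majority base beats deletion
    consensus <- paste(bases[top[keep]], collapse = "")
    # one monomer's worth of columns: identical element LTRs can both be
    # covered even when the circle carries a single LTR copy
    if (nchar(consensus) > round(monomer_len))
      consensus <- substr(consensus, 1L, round(monomer_len))
  }

  structure(list(read_id = read_id, element_id = element_id,
                 monomer_len = as.numeric(monomer_len),
                 n_full_monomers = as.integer(n_full),
                 monomer_intervals = monomer_intervals,
                 junction_supported = junction, consensus = consensus,
                 hits = hits, element_len = elen, pile_full = pile_full,
                 pile_all = pile_all, cov_best = cov_best, read_len = rl,
                 read = read),
            class = "monomer_decomposition")
}

#' @export
print.monomer_decomposition <- function(x, ...) {
  cat(sprintf("concatemer decomposition of %s vs %s: monomer %.0f bp, %d full monomer(s), consensus %d bp\n",
              x$read_id, x$element_id,
              ifelse(is.na(x$monomer_len), NA, x$monomer_len),
              x$n_full_monomers, nchar(x$consensus)))
  invisible(x)
}

#' Classify the eccDNA structure implied by a decomposition
#'
#' Projects the consensus (or the best monomer when fewer than two full
#' monomers exist) onto the element and applies coverage rules:
#' internal coverage <= `solo_internal` with at least one LTR copy is a
#' solo-LTR circle; internal coverage >= `internal_full` with one (two) LTR
#' copies per monomer is a full-length circle with one (two) LTRs;
#' intermediate internal coverage is a truncated circle; anything else is
#' "other". Uncovered internal gaps of at least `min_del` bp inside the
#' covered span are reported as deletions.
#'
#' @param decomp a [decompose_concatemer()] result.
#' @param element annotation row (or list) with element-relative `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end`.
#' @param internal_full,solo_internal,min_del classification thresholds.
#' @return list of class `ecc_structure_call`: element_id, read_id, class,
#'   internal_coverage, n_ltr_copies, deletions (data.frame of
#'   element-relative intervals).
#' @export
classify_structure <- function(decomp, element, internal_full = 0.9,
                               solo_internal = 0.1, min_del = 20L) {
  need <- c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")
  if (!all(need %in% names(element)) ||
      any(vapply(need, function(f) is.na(element[[f]]), logical(1))))
    stop("element has no LTR sub-intervals")
  elen <- decomp$element_len
  ltr5 <- (element$ltr5_start + 1L):element$ltr5_end
  ltr3 <- (element$ltr3_start + 1L):element$ltr3_end
  internal <- if (element$ltr5_end + 1L <= element$ltr3_start)
    (element$ltr5_end + 1L):element$ltr3_start else integer(0)
  cls_call <- function(cls, internal_cov, nltr, deletions) {
    structure(list(element_id = decomp$element_id, read_id = decomp$read_id,
                   class = cls, internal_coverage = internal_cov,
                   n_ltr_copies = nltr, deletions = deletions),
              class = "ecc_structure_call")
  }
  no_del <- data.frame(start = integer(), end = integer())
  if (!nrow(decomp$hits))
    return(cls_call("other", 0, 0L, no_del))

  use_full <- decomp$n_full_monomers >= 1 && !is.null(decomp$pile_full)
  if (use_full) {
    depth <- colSums(decomp$pile_full[1:5, , drop = FALSE])
    nmono <- max(1L, decomp$n_full_monomers)
  } else {
    depth <- decomp$cov_best
    nmono <- 1L
  }
  covered <- depth > 0
  internal_cov <- if (length(internal)) mean(covered[internal]) else 0
  ltr_len <- mean(c(length(ltr5), length(ltr3)))
  # LTR copies per monomer are counted on READ positions: the two identical
  # LTR copies of the element both align to the same read segment, so element
  # -projected depth would double-count a single circle LTR
  mark <- ltr_read_positions(decomp, element)
  if (use_full && nrow(decomp$monomer_intervals)) {
    mi <- decomp$monomer_intervals
    ltr_bases <- sum(vapply(seq_len(nrow(mi)), function(w)
      sum(mark[(mi$start[w] + 1L):mi$end[w]]), numeric(1)))
    nltr <- as.integer(max(0L, min(2L, round(ltr_bases / (ltr_len * nmono)))))
  } else {
    b <- which.max(decomp$hits$score)
    span <- (decomp$hits$target_start[b] + 1L):decomp$hits$target_end[b]
    nltr <- as.integer(max(0L, min(2L, round(sum(mark[span]) / ltr_len))))
  }

  cls <- if (internal_cov <= solo_internal && nltr >= 1L) "solo_LTR"
  else if (internal_cov >= internal_full && nltr == 1L) "full_1LTR"
  else if (internal_cov >= internal_full && nltr >= 2L) "full_2LTR"
  else if (internal_cov > solo_internal && internal_cov < internal_full) "truncated"
  else "other"

  # uncovered internal gaps >= min_del within the covered span
  deletions <- no_del
  span <- range(which(covered))
  if (length(internal) && is.finite(span[1])) {
    gap <- !covered & seq_len(elen) >= span[1] & seq_len(elen) <= span[2] &
      seq_len(elen) %in% internal
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= min_del
    if (any(sel))
      deletions <- data.frame(start = starts[sel] - 1L, end = ends[sel])
  }
  cls_call(cls, internal_cov, nltr, deletions)
}

# mark read positions whose aligned element position falls in an LTR
# (linear interpolation within each hit; exact enough at percent-level error)
ltr_read_positions <- function(decomp, element) {
  rl <- decomp$read_len
  mark <- logical(rl)
  ivs <- list(c(element$ltr5_start, element$ltr5_end),
              c(element$ltr3_start, element$ltr3_end))
  for (i in seq_len(nrow(decomp$hits))) {
    h <- decomp$hits[i, ]
    qs <- h$query_start; qe <- h$query_end
    if (qe <= qs) next
    scale <- (h$target_end - h$target_start) / (qe - qs)
    for (iv in ivs) {
      s <- max(qs, iv[1]); e <- min(qe, iv[2])
      if (e <= s) next
      if (h$strand == "+") {
        rs <- h$target_start + (s - qs) * scale
        re <- h$target_start + (e - qs) * scale
      } else {
        rs <- h$target_start + (qe - e) * scale
        re <- h$target_start + (qe - s) * scale
      }
      lo <- max(1L, floor(rs) + 1L); hi <- min(rl, ceiling(re))
      if (hi >= lo) mark[lo:hi] <- TRUE
    }
  }
  mark
}

#' Consensus divergence of eccDNA monomers from the reference element
#'
#' Piles full-monomer copies from several decompositions onto element
#' coordinates and calls a SNP at columns with depth >= `min_depth` where a
#' single base reaches agreement >= `min_agree` and differs from the
#' reference. Ambiguous or deletion-majority columns are never SNPs. The LTRs
#' are flagged uncovered when their mean alignment depth is below 1, and a
#' contiguous uncovered-or-deleted stretch of >= 20 bp inside an otherwise
#' covered LTR is reported as an LTR deletion.
#'
#' @param decomps list of [decompose_concatemer()] results for one element.
#' @param element_seq reference element sequence (element orientation).
#' @param element annotation row with LTR sub-intervals.
#' @param min_depth minimum column depth.
#' @param min_agree minimum consensus agreement fraction.
#' @param polish when TRUE (default), a second alignment pass against the
#'   first-pass consensus template is run before calling: seeds never span a
#'   mismatch against the reference, so divergent columns otherwise fall in
#'   ambiguously-placed gap regions; realigning to the polished template
#'   restores exact anchoring across them.
#' @return list of class `divergence_report`: element_id, snp_count,
#'   snp_positions (0-based element offsets), ltr_covered, ltr_deletion
#'   (c(start, end) or NULL), mean_depth.
#' @export
consensus_divergence <- function(decomps, element_seq, element, min_depth = 5L,
                                 min_agree = 0.8, polish = TRUE) {
  elen <- nchar(element_seq)
  eid <- if (length(decomps)) decomps[[1]]$element_id else NA_character_
  pool <- function(ds, field) {
    p <- matrix(0L, 7, elen)
    for (d in ds) if (!is.null(d[[field]])) p <- p + d[[field]]
    p
  }
  pile <- pool(decomps, "pile_full")
  pile_all <- pool(decomps, "pile_all")
  if (polish && length(decomps)) {
    # first-pass template: loose majority substitutions on the reference
    refb0 <- strsplit(toupper(element_seq), "")[[1]]
    b4 <- c("A", "C", "G", "T")
    bd <- colSums(pile[1:5, , drop = FALSE])
    tp0 <- apply(pile[1:4, , drop = FALSE], 2, which.max)
    cn0 <- pile[cbind(tp0, seq_len(elen))]
    swap <- bd >= min_depth & cn0 / pmax(bd, 1) >= 0.5 & b4[tp0] != refb0 &
      cn0 > pile[6, ]
    if (any(swap)) {
      tmpl <- refb0
      tmpl[swap] <- b4[tp0[swap]]
      tmpl <- paste(tmpl, collapse = "")
      redo <- lapply(decomps, function(d)
        decompose_concatemer(d$read, tmpl, read_id = d$read_id,
                             element_id = d$element_id))
      pile <- pool(redo, "pile_full")
      pile_all <- pool(redo, "pile_all")
    }
  }
  refb <- strsplit(toupper(element_seq), "")[[1]]
  bases <- c("A", "C", "G", "T")
  depth <- colSums(pile[c(1:4, 6), , drop = FALSE])       # coverage incl. dels
  base_depth <- colSums(pile[1:5, , drop = FALSE])        # base calls only
  top <- apply(pile[1:4, , drop = FALSE], 2, which.max)
  cnt <- pile[cbind(top, seq_len(elen))]
  # agreement over base calls; deletion-majority columns are never SNPs
  agree <- ifelse(base_depth > 0, cnt / base_depth, 0)
  callable <- depth >= min_depth & agree >= min_agree & cnt > pile[6, ]
  snp <- callable & bases[top] != refb
  snp_positions <- which(snp) - 1L

  ltr5 <- (element$ltr5_start + 1L):element$ltr5_end
  ltr3 <- (element$ltr3_start + 1L):element$ltr3_end
  depth_all <- colSums(pile_all[c(1:4, 6), , drop = FALSE])
  ltr_covered <- mean(depth_all[c(ltr5, ltr3)]) >= 1

  ltr_deletion <- NULL
  for (ltr in list(ltr5, ltr3)) {
    if (mean(depth_all[ltr]) < 1) next
    gap <- depth_all[ltr] == 0 | pile_all[6, ltr] > colSums(pile_all[1:4, ltr, drop = FALSE])
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= 20L)
    if (length(sel)) {
      big <- sel[which.max(r$lengths[sel])]
      cand <- c(ltr[1] - 1L + starts[big] - 1L, ltr[1] - 1L + ends[big])
      if (is.null(ltr_deletion) ||
          (cand[2] - cand[1]) > (ltr_deletion[2] - ltr_deletion[1]))
        ltr_deletion <- cand
    }
  }
  structure(list(element_id = eid, snp_count = length(snp_positions),
                 snp_positions = snp_positions, ltr_covered = ltr_covered,
                 ltr_deletion = ltr_deletion,
                 mean_depth = mean(depth)),
            class = "divergence_report")
}

#' Estimate the circle length of a concatemer read without a reference
#'
#' Reference-free periodicity estimate: the modal separation between repeated
#' k-mers within the read (k-mer offset histogram peak), for circles whose
#' element is absent from the reference.
#'
#' @param read read sequence.
#' @param k k-mer length.
#' @param min_period,max_period search range (bp).
#' @param bin histogram bin width (bp).
#' @return estimated period in bp (NA when no periodicity is found).
#' @export
estimate_circle_period <- function(read, k = 13L, min_period = 50L,
                                   max_period = NULL, bin = 10L) {
  read <- as.character(read)
  if (is.null(max_period)) max_period <- floor(nchar(read) / 2)
  if (max_period <= min_period) return(NA_real_)
  anc <- mb_self_anchors(read, as.integer(k), as.integer(min_period),
                         as.integer(max_period), 500L)
  if (!nrow(anc)) return(NA_real_)
  sep <- anc[, 2] - anc[, 1]
  h <- table(round(sep / bin))
  peak <- as.integer(names(h)[which.max(h)])
  inpeak <- sep[abs(sep - peak * bin) <= bin]
  stats::median(inpeak)
}

#' Assign the species-of-origin of a query sequence against a genome panel
#'
#' Locates the best local hit of the query in each panel genome with the
#' built-in aligner, refines it to a global percent identity over the matched
#' locus, and assigns the top genome when its identity reaches
#' `identity_floor` and exceeds the runner-up by at least `min_margin`
#' percentage points; otherwise the call is ambiguous. Ties break
#' deterministically by genome name.
#'
#' @param query query sequence (e.g. a consensus LTR deduced from eccDNA
#'   reads).
#' @param panel named list: genome name -> named character vector of
#'   sequences (or a single sequence, or a FASTA path).
#' @param identity_floor minimum percent identity for assignment.
#' @param min_margin minimum identity margin (points) over the second-best
#'   genome.
#' @param params aligner parameters.
#' @return list of class `origin_call`: query_id, per_genome (data.frame:
#'   genome, best_identity, target_id, target_start, target_end), assigned
#'   (genome name or "ambiguous"), margin.
#' @export
assign_origin <- function(query, panel, identity_floor = 96, min_margin = 1.0,
                          params = aligner_params()) {
  if (!length(panel)) stop("empty genome panel")
  if (is.null(names(panel)) || any(names(panel) == ""))
    stop("panel genomes must be named")
  query <- as.character(query)
  qlen <- nchar(query)
  rows <- list()
  for (g in sort(names(panel))) {
    gen <- panel[[g]]
    if (length(gen) == 1 && nchar(gen[[1]]) < 4096 && file.exists(gen[[1]]))
      gen <- read_fasta(gen[[1]])
    if (is.null(names(gen))) names(gen) <- paste0(g, "_seq", seq_along(gen))
    idx <- build_reference_index(gen, k = params$k)
    hits <- map_long_read(query, idx, params, query_id = "query")
    if (!nrow(hits)) {
      rows[[g]] <- data.frame(genome = g, best_identity = 0,
                              target_id = NA_character_, target_start = NA_integer_,
                              target_end = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    h <- hits[which.max(hits$score), , drop = FALSE]
    # pad the matched locus by the clipped query amounts, then global identity
    tseq <- gen[[h$target_id]]
    pad_l <- h$query_start
    pad_r <- qlen - h$query_end
    if (h$strand == "-") { tmp <- pad_l; pad_l <- pad_r; pad_r <- tmp }
    ts <- max(0L, h$target_start - pad_l)
    te <- min(nchar(tseq), h$target_end + pad_r)
    win <- substr(tseq, ts + 1L, te)
    if (h$strand == "-") win <- revcomp(win)
    idy <- suppressWarnings(global_identity(query, win,
                                            band_slack = max(60L, abs(qlen - nchar(win)) + 20L),
                                            params))
    rows[[g]] <- data.frame(genome = g, best_identity = idy,
                            target_id = h$target_id, target_start = ts,
                            target_end = te, stringsAsFactors = FALSE)
  }
  per_genome <- do.call(rbind, rows)
  rownames(per_genome) <- NULL
  ord <- order(-per_genome$best_identity, per_genome$genome)
  best <- per_genome[ord[1], ]
  margin <- if (nrow(per_genome) > 1)
    best$best_identity - per_genome$best_identity[ord[2]] else Inf
  assigned <- if (best$best_identity >= identity_floor && margin >= min_margin)
    best$genome else "ambiguous"
  structure(list(query_id = "query", per_genome = per_genome,
                 assigned = assigned, margin = margin),
            class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("origin call: %s (margin %.1f points)\n", x$assigned,
              ifelse(is.finite(x$margin), x$margin, NA)))
  print(x$per_genome[order(-x$per_genome$best_identity), ])
  invisible(x)
}

#' Dot-plot coordinates of monomer alignments against the element
#'
#' Emits (read_pos, element_pos) pairs of aligned bases for every hit of a
#' decomposition, for plotting concatemer structure.
#'
#' @param decomp a [decompose_concatemer()] result.
#' @return data.frame with read_pos, element_pos, hit (both 0-based).
#' @export
monomer_dotplot_coords <- function(decomp) {
  out <- list()
  for (i in seq_len(nrow(decomp$hits))) {
    h <- decomp$hits[i, ]
    ops <- cigar_ops(h$cigar)
    # cigar walks the oriented element (query) against the read (target)
    qp <- if (h$strand == "+") h$query_start else decomp$element_len - h$query_end
    tp <- h$target_start
    qs <- integer(0); ts <- integer(0)
    for (r in seq_len(nrow(ops))) {
      len <- ops$len[r]
      if (ops$op[r] %in% c("=", "X", "M")) {
        qs <- c(qs, qp + seq_len(len) - 1L)
        ts <- c(ts, tp + seq_len(len) - 1L)
        qp <- qp + len; tp <- tp + len
      } else if (ops$op[r] == "I") qp <- qp + len
      else tp <- tp + len
    }
    if (h$strand == "-") qs <- decomp$element_len - qs - 1L
    out[[i]] <- data.frame(read_pos = ts, element_pos = qs, hit = i)
  }
  if (!length(out)) return(data.frame(read_pos = integer(),
                                      element_pos = integer(), hit = integer()))
  do.call(rbind, out)
}
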