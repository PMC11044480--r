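#' Naive pileup SNP calling from long-read alignments
#'
#' Per-column pileup of primary alignments; a SNP is emitted where the top
#' non-reference base reaches allele fraction >= `min_af` at depth >=
#' `min_depth` (haploid-style calling for the synthetic donor).
#'
#' @param alignments `mb_alignments` table against `reference`.
#' @param reads named character vector of read sequences (read ids must match
#'   `query_id`).
#' @param reference named character vector of chromosomes.
#' @param min_depth minimum pileup depth.
#' @param min_af minimum non-reference allele fraction.
#' @return data.frame: chrom, pos (0-based), ref, alt, depth, af.
#' @export
call_snps_naive <- function(alignments, reads, reference, min_depth = 5L,
                            min_af = 0.7) {
  prim <- alignments[alignments$is_primary %in% TRUE, , drop = FALSE]
  if (nrow(prim) && !all(prim$target_id %in% names(reference)))
    stop("alignment references a chromosome absent from the reference")
  out <- list()
  for (ch in names(reference)) {
    L <- nchar(reference[[ch]])
    rows <- prim[prim$target_id == ch, , drop = FALSE]
    if (!nrow(rows)) next
    orient <- lapply(seq_len(nrow(rows)), function(i)
      orient_for_pileup(rows[i, ], reads[[rows$query_id[i]]], on = "target"))
    pile <- mb_pileup(L, vapply(orient, `[[`, numeric(1), "tstart"),
                      vapply(orient, `[[`, numeric(1), "qstart"),
                      vapply(orient, `[[`, character(1), "cigar"),
                      vapply(orient, `[[`, character(1), "qseq"))
    depth <- colSums(pile[c(1:4, 6), , drop = FALSE])
    cand <- which(depth >= min_depth)
    if (!length(cand)) next
    top <- apply(pile[1:4, cand, drop = FALSE], 2, which.max)
    cnt <- pile[cbind(top, cand)]
    af <- cnt / depth[cand]
    bases <- c("A", "C", "G", "T")
    refb <- substring(reference[[ch]], cand, cand)
    keep <- af >= min_af & bases[top] != refb & refb %in% bases
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, pos = cand[keep] - 1L,
                              ref = refb[keep], alt = bases[top[keep]],
                              depth = as.integer(depth[cand][keep]),
                              af = af[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(), af = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed SNP density track
#'
#' Fixed non-overlapping tiling of each chromosome; the density of the last
#' partial window is scaled by its true width. The genome-wide median density
#' is computed over full windows only.
#'
#' @param variants data.frame with chrom and pos (0-based).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @return An object of class `snp_density`: `windows` (data.frame chrom,
#'   win_start, win_end, count, density in SNPs/Mb), `window_size`,
#'   `genome_median`.
#' @export
snp_density_windows <- function(variants, chrom_lengths, window_size = 1e6) {
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    if (nrow(v) && any(v$pos >= L | v$pos < 0))
      stop("variant beyond chromosome length on ", ch)
    n_win <- ceiling(L / window_size)
    ws <- (seq_len(n_win) - 1) * window_size
    we <- pmin(ws + window_size, L)
    cnt <- integer(n_win)
    if (nrow(v)) {
      tab <- table(floor(v$pos / window_size))
      cnt[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    out[[ch]] <- data.frame(chrom = ch, win_start = ws, win_end = we,
                            count = cnt, density = cnt * 1e6 / (we - ws),
                            full = (we - ws) == window_size,
                            stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  med <- if (any(windows$full)) stats::median(windows$density[windows$full]) else 0
  structure(list(windows = windows, window_size = window_size,
                 genome_median = med),
            class = "snp_density")
}

#' Segment introgressions from a SNP density track
#'
#' Left-to-right scan for maximal runs of windows with density >=
#' `fold_threshold` times the genome median, allowing up to `max_gap`
#' consecutive sub-threshold windows inside a run. Runs spanning fewer than
#' `min_windows` windows are dropped. When the genome median is zero the scan
#' falls back to an absolute density threshold with a warning.
#'
#' @param track a [snp_density_windows()] result.
#' @param fold_threshold calling threshold as a ratio to the genome median.
#' @param min_windows minimum run length in windows.
#' @param max_gap maximum consecutive sub-threshold windows bridged.
#' @param absolute_density fallback threshold (SNPs/Mb) when the median is 0.
#' @return data.frame: chrom, start, end (bp, window-aligned, 0-based
#'   half-open), n_windows, mean_fold.
#' @export
segment_introgressions <- function(track, fold_threshold = 5, min_windows = 3L,
                                   max_gap = 1L, absolute_density = 50) {
  med <- track$genome_median
  if (med <= 0) {
    warning("genome median density is zero; using absolute threshold of ",
            absolute_density, " SNPs/Mb")
    thr <- absolute_density
  } else thr <- fold_threshold * med
  segs <- list()
  for (ch in unique(track$windows$chrom)) {
    w <- track$windows[track$windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$win_start), , drop = FALSE]
    hot <- w$density >= thr
    run_start <- NA_integer_
    last_hot <- NA_integer_
    gap <- 0L
    close_run <- function(rs, re) {
      n <- re - rs + 1L
      if (n < min_windows) return(NULL)
      dens <- w$density[rs:re]
      data.frame(chrom = ch, start = w$win_start[rs], end = w$win_end[re],
                 n_windows = n,
                 mean_fold = if (med > 0) mean(dens) / med else NA_real_,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(w))) {
      if (hot[i]) {
        if (is.na(run_start)) run_start <- i
        last_hot <- i
        gap <- 0L
      } else if (!is.na(run_start)) {
        gap <- gap + 1L
        if (gap > max_gap) {
          s <- close_run(run_start, last_hot)
          if (!is.null(s)) segs[[length(segs) + 1L]] <- s
          run_start <- NA_integer_
          gap <- 0L
        }
      }
    }
    if (!is.na(run_start)) {
      s <- close_run(run_start, last_hot)
      if (!is.null(s)) segs[[length(segs) + 1L]] <- s
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), mean_fold = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

# single-linkage 1-d clustering of sorted positions; gap > radius splits
cluster_positions <- function(pos, radius) {
  ord <- order(pos)
  grp <- cumsum(c(TRUE, diff(pos[ord]) > radius))
  split(ord, grp)
}

#' Call non-reference TE insertions (TEIs) from long-read alignments
#'
#' Evidence per read: (a) split alignments of one read on the same chromosome
#' and strand whose query intervals are separated by at least `min_insert` bp
#' while the reference intervals nearly abut (a small negative reference gap
#' is the target-site duplication); (b) alignment cigars containing an
#' insertion op of at least `min_insert` bp; (c) clipped tails of at least
#' `min_insert` bp that re-align to the TE library. Breakpoints are clustered
#' within `cluster_radius` bp; a call needs `min_support` reads or more. The
#' inserted-sequence representative is matched to the library and a family is
#' assigned at 80% identity or better over 80% of the element length. The TSD
#' is the duplicated reference flank (3-8 bp) at the breakpoint.
#'
#' @param alignments `mb_alignments` of WGS reads vs the reference.
#' @param reads named character vector of read sequences.
#' @param te_library named character vector of TE element sequences (or NULL:
#'   families stay unassigned and clips cannot vote).
#' @param reference named character vector of chromosomes (for TSD lookup).
#' @param min_insert minimum inserted length (bp).
#' @param min_support minimum supporting reads.
#' @param cluster_radius breakpoint clustering radius (bp).
#' @param params aligner parameters for library matching.
#' @return data.frame: chrom, position (0-based reference base immediately
#'   left of the insertion), support, inserted_len, family, family_identity,
#'   tsd.
#' @export
call_teis <- function(alignments, reads, te_library, reference,
                      min_insert = 500L, min_support = 3L,
                      cluster_radius = 50L, params = aligner_params()) {
  ev <- list()
  # side: which junction the evidence pins down on the reference --
  # "high" = end of the left-flank alignment (position qa on the oriented
  # read), "low" = start of the right-flank alignment (position qb),
  # "both" = a split pair carrying the two junctions on one read
  add_ev <- function(chrom, bp, read, ins_len, tsd_len, insert_seq,
                     type, side = "none", qa = NA_integer_,
                     qb = NA_integer_, strand = NA_character_) {
    ev[[length(ev) + 1L]] <<- data.frame(chrom = chrom, bp = bp, read = read,
                                         ins_len = ins_len, tsd_len = tsd_len,
                                         insert_seq = insert_seq, type = type,
                                         side = side, qa = qa, qb = qb,
                                         strand = strand,
                                         stringsAsFactors = FALSE)
  }
  lib_idx <- if (length(te_library))
    build_reference_index(te_library, k = params$k) else NULL

  # the inserted sequence abuts the breakpoint, so the library hit must
  # involve the clip's breakpoint-proximal edge (a TE merely embedded in
  # flanking sequence does not qualify)
  clip_maps_to_library <- function(seq, proximal) {
    if (is.null(lib_idx) || nchar(seq) < params$min_aln_len) return(FALSE)
    h <- map_long_read(seq, lib_idx, params)
    if (!nrow(h)) return(FALSE)
    span_ok <- (h$query_end - h$query_start) >= min(200L, 0.5 * nchar(seq))
    prox_ok <- if (proximal == "start") h$query_start <= 100L else
      h$query_end >= nchar(seq) - 100L
    any(span_ok & prox_ok)
  }

  for (rid in unique(alignments$query_id)) {
    rows <- alignments[alignments$query_id == rid, , drop = FALSE]
    rows <- rows[order(rows$query_start), , drop = FALSE]
    rseq <- reads[[rid]]
    # keep one record per query region (primary + supplementary style):
    # secondaries re-mapping the same read stretch to sister repeat copies
    # must not pair into spurious split evidence
    ord <- order(-rows$score)
    keep <- rep(TRUE, nrow(rows))
    for (i in seq_along(ord)) {
      if (!keep[ord[i]]) next
      if (i == length(ord)) break
      for (j in ord[(i + 1L):length(ord)]) {
        if (!keep[j]) next
        ov <- min(rows$query_end[ord[i]], rows$query_end[j]) -
          max(rows$query_start[ord[i]], rows$query_start[j])
        if (ov > 0.5 * (rows$query_end[j] - rows$query_start[j]))
          keep[j] <- FALSE
      }
    }
    srows <- rows[keep, , drop = FALSE]
    srows <- srows[order(srows$query_start), , drop = FALSE]
    # (a) split-read pairs: two supplementary records whose query intervals
    # are separated while the reference intervals nearly abut
    if (nrow(srows) > 1) {
      for (i in seq_len(nrow(srows) - 1L)) for (j in (i + 1L):nrow(srows)) {
        r1 <- srows[i, ]; r2 <- srows[j, ]
        if (r1$target_id != r2$target_id || r1$strand != r2$strand) next
        qgap <- r2$query_start - r1$query_end
        if (qgap < min_insert) next
        if (r1$strand == "+") {
          tgap <- r2$target_start - r1$target_end
          bp <- r2$target_start
          qa <- r1$query_end; qb <- r2$query_start
        } else {
          tgap <- r1$target_start - r2$target_end
          bp <- r1$target_start
          L <- r1$query_len
          qa <- L - r2$query_start; qb <- L - r1$query_end
        }
        if (tgap < -30 || tgap > 100) next
        tsd_len <- if (tgap <= -3 && tgap >= -20) -tgap else NA_integer_
        ins <- substr(rseq, r1$query_end + 1L, r2$query_start)
        if (r1$strand == "-") ins <- revcomp(ins)
        add_ev(r1$target_id, bp, rid, qgap, tsd_len, ins, "split", "both",
               qa, qb, r1$strand)
      }
    }
    # (b) large insertion ops inside one alignment
    prim <- rows[rows$is_primary %in% TRUE, , drop = FALSE]
    for (i in seq_len(nrow(prim))) {
      ops <- cigar_ops(prim$cigar[i])
      big <- which(ops$op == "I" & ops$len >= min_insert)
      if (!length(big)) next
      tp <- prim$target_start[i]
      qp <- 0L
      for (r in seq_len(nrow(ops))) {
        if (r %in% big) {
          oriented <- if (prim$strand[i] == "-") revcomp(rseq) else rseq
          oq <- if (prim$strand[i] == "-")
            prim$query_len[i] - prim$query_end[i] else prim$query_start[i]
          ins <- substr(oriented, oq + qp + 1L, oq + qp + ops$len[r])
          add_ev(prim$target_id[i], tp, prim$query_id[i], ops$len[r],
                 NA_integer_, ins, "cigar")
        }
        if (ops$op[r] %in% c("=", "X", "M")) { tp <- tp + ops$len[r]; qp <- qp + ops$len[r] }
        else if (ops$op[r] == "I") qp <- qp + ops$len[r]
        else tp <- tp + ops$len[r]
      }
    }
    # (c) clipped tails of the primary alignment re-aligning to the library
    if (nrow(prim) >= 1L) {
      r1 <- prim[1, ]
      lclip <- r1$query_start
      rclip <- r1$query_len - r1$query_end
      L <- r1$query_len
      if (lclip >= min_insert) {
        seq <- substr(rseq, 1L, lclip)
        if (clip_maps_to_library(seq, proximal = "end")) {
          if (r1$strand == "+")
            add_ev(r1$target_id, r1$target_start, rid, lclip, NA_integer_,
                   seq, "clip", "low", qb = r1$query_start,
                   strand = r1$strand)
          else
            add_ev(r1$target_id, r1$target_end, rid, lclip, NA_integer_,
                   seq, "clip", "high", qa = L - r1$query_start,
                   strand = r1$strand)
        }
      }
      if (rclip >= min_insert) {
        seq <- substr(rseq, r1$query_end + 1L, L)
        if (clip_maps_to_library(seq, proximal = "start")) {
          if (r1$strand == "+")
            add_ev(r1$target_id, r1$target_end, rid, rclip, NA_integer_,
                   seq, "clip", "high", qa = r1$query_end,
                   strand = r1$strand)
          else
            add_ev(r1$target_id, r1$target_start, rid, rclip, NA_integer_,
                   seq, "clip", "low", qb = L - r1$query_end,
                   strand = r1$strand)
        }
      }
    }
  }
  empty <- data.frame(chrom = character(), position = integer(),
                      support = integer(), inserted_len = integer(),
                      family = character(), family_identity = numeric(),
                      tsd = character(), stringsAsFactors = FALSE)
  if (!length(ev)) return(empty)
  ev <- do.call(rbind, ev)
  calls <- list()
  for (ch in unique(ev$chrom)) {
    e <- ev[ev$chrom == ch, , drop = FALSE]
    for (cl in cluster_positions(e$bp, cluster_radius)) {
      sub <- e[cl, , drop = FALSE]
      support <- length(unique(sub$read))
      if (support < min_support) next
      # split evidence carries the cleanest breakpoints; clips are offset by
      # the (unknown) TSD and only add support when splits exist
      core <- sub[sub$type != "clip", , drop = FALSE]
      if (!nrow(core)) core <- sub
      pos <- as.integer(round(stats::median(core$bp)))
      ins_len <- as.integer(round(stats::median(core$ins_len)))
      if (ins_len < min_insert) next
      rep_seq <- core$insert_seq[which.max(nchar(core$insert_seq))]
      family <- "unassigned"; fid <- NA_real_
      if (!is.null(lib_idx) && nchar(rep_seq) >= params$min_aln_len) {
        h <- map_long_read(rep_seq, lib_idx, params)
        if (nrow(h)) {
          h$cov <- (h$target_end - h$target_start) / h$target_len
          h$idy <- 100 * h$matches / h$aln_columns
          ok <- h[h$idy >= 80 & h$cov >= 0.8, , drop = FALSE]
          if (nrow(ok)) {
            bestr <- ok[which.max(ok$score), ]
            family <- bestr$target_id
            fid <- bestr$idy
          }
        }
      }
      tsd <- NA_character_
      # micro-homology-aware refinement: alignment ends slide across the
      # junctions (extensions tolerate occasional matches and mismatches), so
      # the exact site and TSD are recovered from the duplicated flank as it
      # appears on the reads themselves. The left-junction copy (TSD1, ending
      # at qa on a "high"/"both" read) and the right-junction copy (TSD2,
      # starting after qb on a "low"/"both" read) must both match the
      # reference site.
      refined <- FALSE
      hi_src <- sub[sub$side %in% c("both", "high") & !is.na(sub$qa), , drop = FALSE]
      lo_src <- sub[sub$side %in% c("both", "low") & !is.na(sub$qb), , drop = FALSE]
      if (nrow(hi_src) && nrow(lo_src)) {
        A <- hi_src[order(!(hi_src$side == "both" & !is.na(hi_src$tsd_len)),
                          -hi_src$ins_len)[1], ]
        B <- lo_src[order(lo_src$side != "both", -lo_src$ins_len)[1], ]
        RA <- reads[[A$read]]
        if (A$strand == "-") RA <- revcomp(RA)
        RB <- reads[[B$read]]
        if (B$strand == "-") RB <- revcomp(RB)
        s2 <- B$bp
        # the high junction sits t + x + y bases right of the low one; that
        # geometry pins down the admissible (t, x, y) combinations. A split
        # row stores the low-side position, so its span is the raw tsd_len
        # (= -reference gap); a high-side clip stores e1 directly.
        d <- as.integer(if (A$side == "both") A$tsd_len else A$bp - s2)
        for (t in 8:3) {
          if (refined) break
          for (y in 0:15) {
            if (refined) break
            x <- d - t - y
            if (is.na(x) || x < 0 || x > 15) next
            tsd1 <- substr(RA, A$qa - x - t + 1L, A$qa - x)
            tsd2 <- substr(RB, B$qb + y + 1L, B$qb + y + t)
            refg <- substr(reference[[ch]], s2 + y + 1L, s2 + y + t)
            if (nchar(tsd1) == t && tsd1 == tsd2 && tsd1 == refg) {
              pos <- as.integer(s2 + y)
              tsd <- refg
              refined <- TRUE
            }
          }
        }
      }
      if (!refined) {
        tl <- sub$tsd_len[!is.na(sub$tsd_len)]
        if (length(tl)) {
          tlen <- as.integer(round(stats::median(tl)))
          tsd <- substr(reference[[ch]], pos + 1L, pos + tlen)
        }
      }
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, position = pos, support = support,
        inserted_len = ins_len, family = family, family_identity = fid,
        tsd = tsd, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res <- res[order(res$chrom, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Check an element locus (with flanks) against another assembly
#'
#' Extracts the element with `flank` bp of flanking sequence, and the
#' flank-joined empty site (element excised), and reports whether each is
#' present in the other assembly (best local hit covering >= `min_cov` of the
#' query at >= `min_identity` percent identity).
#'
#' @param genome named character vector holding the element's assembly.
#' @param element annotation row (chrom, start, end).
#' @param other named character vector of the assembly to search.
#' @param flank flank length (bp).
#' @param min_identity,min_cov presence thresholds.
#' @param params aligner parameters.
#' @return list: locus_present, empty_site_present, locus_identity,
#'   empty_site_identity.
#' @export
flank_check <- function(genome, element, other, flank = 2000L,
                        min_identity = 80, min_cov = 0.8,
                        params = aligner_params()) {
  chrom <- genome[[element$chrom]]
  s <- max(0L, element$start - flank)
  e <- min(nchar(chrom), element$end + flank)
  locus <- substr(chrom, s + 1L, e)
  empty_site <- paste0(substr(chrom, s + 1L, element$start),
                       substr(chrom, element$end + 1L, e))
  idx <- build_reference_index(other, k = params$k)
  check <- function(q) {
    h <- map_long_read(q, idx, params)
    if (!nrow(h)) return(list(present = FALSE, identity = NA_real_))
    h <- h[which.max(h$query_end - h$query_start), ]
    cov <- (h$query_end - h$query_start) / nchar(q)
    idy <- 100 * h$matches / h$aln_columns
    list(present = cov >= min_cov && idy >= min_identity, identity = idy)
  }
  a <- check(locus)
  b <- check(empty_site)
  list(locus_present = a$present, empty_site_present = b$present,
       locus_identity = a$identity, empty_site_identity = b$identity)
}
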