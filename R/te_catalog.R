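#' De novo detection of LTR pairs
#'
#' Scans each chromosome for pairs of nearby direct repeats: exact k-mer
#' anchors between positions separated by `min_internal` to `max_element_len`
#' bp are clustered by diagonal (separation), candidate repeat intervals of at
#' least `min_ltr_len` are verified by banded global alignment, and candidates
#' overlapping a higher-identity candidate are dropped. A target-site
#' duplication is recorded when the 4-6 bp flanks match, but is not required.
#'
#' @param genome named character vector (or DNAStringSet) of chromosomes.
#' @param min_ltr_len minimum LTR length (bp).
#' @param max_element_len maximum element span (bp).
#' @param min_identity minimum LTR pair percent identity.
#' @param min_internal minimum internal region (bp) between the repeats.
#' @param k anchor k-mer length.
#' @param params scoring parameters for identity ([aligner_params()]).
#' @return data.frame of detected elements: chrom, start, end, strand,
#'   ltr5_start/end, ltr3_start/end (element-relative), ltr_identity, tsd.
#' @export
detect_ltr_pairs <- function(genome, min_ltr_len = 100L, max_element_len = 15000L,
                             min_identity = 85, min_internal = 500L, k = 13L,
                             params = aligner_params()) {
  genome <- as_chr_seqs(genome)
  out <- list()
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    anc <- mb_self_anchors(seq, as.integer(k), as.integer(min_internal),
                           as.integer(max_element_len), 200L)
    if (!nrow(anc)) next
    d <- anc[, 2] - anc[, 1]
    ord <- order(d, anc[, 1])
    anc <- anc[ord, , drop = FALSE]
    d <- d[ord]
    # cluster anchors by separation (diagonal) and adjacency along the sequence
    brk <- c(TRUE, diff(d) > 50)
    grp0 <- cumsum(brk)
    cand <- list()
    for (g in split(seq_len(nrow(anc)), grp0)) {
      a <- anc[g, , drop = FALSE]
      a <- a[order(a[, 1]), , drop = FALSE]
      # split where consecutive anchors are far apart
      sp <- cumsum(c(TRUE, diff(a[, 1]) > 200))
      for (s in split(seq_len(nrow(a)), sp)) {
        b <- a[s, , drop = FALSE]
        len1 <- max(b[, 1]) + k - min(b[, 1])
        if (len1 < min_ltr_len) next
        cand[[length(cand) + 1L]] <- c(min(b[, 1]), max(b[, 1]) + k,
                                       min(b[, 2]), max(b[, 2]) + k)
      }
    }
    if (!length(cand)) next
    for (cd in cand) {
      l1s <- cd[1]; l1e <- cd[2]; l2s <- cd[3]; l2e <- cd[4]
      if (l2s - l1e < min_internal) next
      if (l2e - l1s > max_element_len) next
      s1 <- substr(seq, l1s + 1L, l1e)
      s2 <- substr(seq, l2s + 1L, l2e)
      idy <- suppressWarnings(global_identity(s1, s2, band_slack = 60L, params))
      if (idy < min_identity) next
      tsd <- NA_character_
      for (tl in 6:4) {
        fl <- substr(seq, l1s - tl + 1L, l1s)
        fr <- substr(seq, l2e + 1L, l2e + tl)
        if (nchar(fl) == tl && fl == fr) { tsd <- fl; break }
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = l1s, end = l2e, strand = "+",
        ltr5_start = 0L, ltr5_end = l1e - l1s,
        ltr3_start = l2s - l1s, ltr3_end = l2e - l1s,
        ltr_identity = idy, tsd = tsd, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      ltr5_start = integer(), ltr5_end = integer(),
                      ltr3_start = integer(), ltr3_end = integer(),
                      ltr_identity = numeric(), tsd = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # resolve overlaps: keep the highest-identity candidate
  res <- res[order(-res$ltr_identity, res$chrom, res$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(res)) > i & res$chrom == res$chrom[i] &
                 res$start < res$end[i] & res$end > res$start[i])
    keep[j] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(match(res$chrom, names(genome)), res$start), , drop = FALSE]
  res <- cbind(id = sprintf("LTRpair%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Extract 5' LTR sequences for an annotation table
#' @param genome named character vector of chromosomes.
#' @param ann TE annotation data.frame (element-relative LTR intervals).
#' @return named character vector of 5' LTR sequences (element orientation).
#' @export
ltr5_sequences <- function(genome, ann) {
  out <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    es <- substr(genome[[ann$chrom[i]]], ann$start[i] + 1L, ann$end[i])
    if (ann$strand[i] == "-") es <- revcomp(es)
    out[i] <- substr(es, ann$ltr5_start[i] + 1L, ann$ltr5_end[i])
  }
  names(out) <- ann$id
  out
}

#' Cluster elements into families by LTR identity
#'
#' Single-linkage clustering on pairwise global identity of the 5' LTR
#' sequences: elements joined by any chain of pairs with identity >=
#' `linkage_threshold` fall in one family. Labels are deterministic, ordered by
#' each family's leftmost member in the input order.
#'
#' @param ltr_seqs named character vector of LTR sequences.
#' @param linkage_threshold percent identity threshold for linking.
#' @param params scoring parameters.
#' @return list with `family` (named character vector of labels), `identity`
#'   (pairwise identity matrix) and `tree` (neighbour-joining tree on
#'   100 - identity distances, an [ape::phylo], NULL for < 3 elements).
#' @export
cluster_families <- function(ltr_seqs, linkage_threshold = 80,
                             params = aligner_params()) {
  n <- length(ltr_seqs)
  if (!n) stop("no LTR sequences supplied")
  ids <- names(ltr_seqs)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idy <- suppressWarnings(
        global_identity(ltr_seqs[[i]], ltr_seqs[[j]],
                        band_slack = max(60L, abs(nchar(ltr_seqs[[i]]) -
                                                    nchar(ltr_seqs[[j]])) + 20L),
                        params))
      idm[i, j] <- idm[j, i] <- idy
    }
  }
  # connected components of the identity >= threshold graph (single linkage)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (idm[i, j] >= linkage_threshold && comp[j] != comp[i]) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  first <- tapply(seq_len(n), comp, min)
  lab <- stats::setNames(sprintf("FAM%d", rank(first)), names(first))
  family <- stats::setNames(unname(lab[as.character(comp)]), ids)
  tree <- NULL
  if (n >= 3) {
    dm <- stats::as.dist(100 - idm)
    tree <- tryCatch(ape::nj(dm), error = function(e) NULL)
  }
  list(family = family, identity = idm, tree = tree)
}

#' Six-frame open reading frame scan
#'
#' Scans all six reading frames for ATG..stop ORFs. Lengths are reported in
#' codons excluding the stop codon. Results are sorted by length, descending.
#'
#' @param seq DNA sequence (A/C/G/T/IUPAC letters).
#' @param min_codons minimum ORF length in codons.
#' @return data.frame with frame (+1,+2,+3,-1,-2,-3 as strings), start, end
#'   (0-based half-open on the forward strand of `seq`, stop codon included in
#'   the interval), codons.
#' @export
scan_orfs <- function(seq, min_codons = 300L) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTRYSWKMBDHVN]", seq)) stop("non-IUPAC character in sequence")
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3
      if (ncod < 2) next
      cods <- substring(s, off + 1L + 3L * (0:(ncod - 1L)),
                        off + 3L + 3L * (0:(ncod - 1L)))
      is_stop <- cods %in% STOP_CODONS
      is_atg <- cods == "ATG"
      # for each ATG, the next stop at or after it in the same frame
      stop_idx <- which(is_stop)
      open <- -1L
      for (i in seq_len(ncod)) {
        if (open < 0 && is_atg[i]) open <- i
        if (open > 0 && is_stop[i]) {
          codons <- i - open
          if (codons >= min_codons) {
            # coordinates on the scanned strand, then flip for '-'
            s0 <- off + 3L * (open - 1L)
            e0 <- off + 3L * i
            if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
            out[[length(out) + 1L]] <- data.frame(
              frame = paste0(strand, off + 1L), start = s0, end = e0,
              codons = codons, stringsAsFactors = FALSE)
          }
          open <- -1L
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = character(), start = integer(), end = integer(),
                      codons = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$codons, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the element catalogue table (families TSV)
#'
#' Combines LTR identity, family assignment and the longest ORF per element.
#'
#' @param genome named character vector of chromosomes.
#' @param ann TE annotation data.frame.
#' @param linkage_threshold family linkage threshold (percent identity).
#' @param min_codons minimum reported ORF length.
#' @param params scoring parameters.
#' @return list with `catalog` (data.frame: id, family, ltr_identity,
#'   longest_orf_codons), `clustering` (result of [cluster_families()]).
#' @export
te_catalog <- function(genome, ann, linkage_threshold = 80, min_codons = 300L,
                       params = aligner_params()) {
  ltrs <- ltr5_sequences(genome, ann)
  cl <- cluster_families(ltrs, linkage_threshold, params)
  ltr_id <- numeric(nrow(ann))
  longest <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    es <- substr(genome[[ann$chrom[i]]], ann$start[i] + 1L, ann$end[i])
    if (ann$strand[i] == "-") es <- revcomp(es)
    l5 <- substr(es, ann$ltr5_start[i] + 1L, ann$ltr5_end[i])
    l3 <- substr(es, ann$ltr3_start[i] + 1L, ann$ltr3_end[i])
    ltr_id[i] <- suppressWarnings(global_identity(l5, l3, band_slack = 60L, params))
    o <- scan_orfs(es, min_codons = min_codons)
    longest[i] <- if (nrow(o)) o$codons[1] else 0L
  }
  list(catalog = data.frame(id = ann$id, family = unname(cl$family[ann$id]),
                            ltr_identity = ltr_id,
                            longest_orf_codons = longest,
                            stringsAsFactors = FALSE),
       clustering = cl)
}
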