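#' Aligner parameters
#'
#' Parameters of the built-in seed-chain-extend long-read aligner and of the
#' banded global aligner used for percent identity. Defaults are tuned for
#' nanopore-like reads with up to ~10% error at desk scale.
#'
#' @param k exact seed length in bp (>= 8).
#' @param max_seed_gap maximum gap (bp, on either sequence) between consecutive
#'   chained seeds before a chain is split.
#' @param band_width diagonal bandwidth (bp) used when clustering seed anchors.
#' @param match,mismatch match reward and mismatch penalty (mismatch negative).
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + gap_extend * L`.
#' @param min_chain_seeds minimum number of seed anchors supporting a chain.
#' @param min_aln_len minimum query span (bp) of a reported alignment.
#' @param max_occ seeds occurring more often than this in the reference are
#'   skipped (repeat masking).
#' @param max_ext maximum unanchored extension (bp) beyond the seed chain.
#' @param max_hits maximum number of alignment records returned per read for
#'   one query region.
#' @param max_split_hits additional records admitted because they cover a
#'   query region no better record covers (split-read flanks, further
#'   concatemer monomers); 0 keeps only the best-region records.
#' @return An object of class `aligner_params` (a validated list).
#' @export
aligner_params <- function(k = 13L, max_seed_gap = 500L, band_width = 100L,
                           match = 1L, mismatch = -2L, gap_open = 2L,
                           gap_extend = 1L, min_chain_seeds = 3L,
                           min_aln_len = 50L, max_occ = 200L, max_ext = 400L,
                           max_hits = 100L, max_split_hits = 100L) {
  p <- list(k = as.integer(k), max_seed_gap = as.integer(max_seed_gap),
            band_width = as.integer(band_width), match = as.integer(match),
            mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            min_chain_seeds = as.integer(min_chain_seeds),
            min_aln_len = as.integer(min_aln_len),
            max_occ = as.integer(max_occ), max_ext = as.integer(max_ext),
            max_hits = as.integer(max_hits),
            max_split_hits = as.integer(max_split_hits))
  if (p$k < 8L) stop("seed length k must be >= 8")
  for (f in c("max_seed_gap", "band_width", "min_chain_seeds", "min_aln_len",
              "max_occ", "max_ext", "max_hits"))
    if (p[[f]] <= 0L) stop(sprintf("'%s' must be positive", f))
  if (p$mismatch >= 0L) stop("'mismatch' must be negative")
  structure(p, class = "aligner_params")
}

as_chr_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  if (is.null(names(x)) || any(names(x) == ""))
    stop("sequences must be named")
  x
}

#' Build a k-mer index over a reference sequence set
#'
#' @param seqs a named character vector or a [Biostrings::DNAStringSet].
#' @param k seed length in bp.
#' @return An object of class `mb_index` wrapping the compiled index.
#' @export
build_reference_index <- function(seqs, k = 13L) {
  seqs <- as_chr_seqs(seqs)
  if (any(nchar(seqs) == 0)) stop("reference contains an empty sequence")
  ptr <- mb_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, names = names(seqs),
                 lengths = stats::setNames(nchar(seqs), names(seqs)),
                 k = as.integer(k)),
            class = "mb_index")
}

#' @export
print.mb_index <- function(x, ...) {
  cat(sprintf("k-mer index (k=%d) over %d sequence(s), %s bp total\n",
              x$k, length(x$names), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

stopifnot_index <- function(index) {
  if (!inherits(index, "mb_index"))
    stop("reference index missing: build one with build_reference_index()")
}

#' Map one long read against an indexed reference
#'
#' Seed-chain-extend local alignment. Seeds are exact k-mers of the index;
#' anchors are clustered by diagonal, chained co-linearly, and the chain is
#' completed by banded dynamic programming between seeds and local extension at
#' the ends. All local alignments above the reporting thresholds are returned;
#' exactly one record (highest score; ties broken by lowest target name, then
#' lowest target start) is flagged primary. Multiple hits of one read to tandem
#' copies of a target region are reported as separate records.
#'
#' Coordinates are 0-based half-open. Query coordinates always refer to the
#' original read; the cigar describes the oriented (strand-matched) query
#' against the forward target.
#'
#' @param read a single DNA sequence (character).
#' @param index an `mb_index` from [build_reference_index()].
#' @param params an [aligner_params()] object.
#' @param query_id identifier recorded in the output.
#' @return A data.frame of class `mb_alignments`, one row per alignment, with
#'   columns query_id, query_len, query_start, query_end, strand, target_id,
#'   target_len, target_start, target_end, matches, aln_columns, score,
#'   n_seeds, cigar, is_primary.
#' @export
map_long_read <- function(read, index, params = aligner_params(),
                          query_id = "query") {
  stopifnot_index(index)
  read <- as.character(read)
  if (length(read) != 1L) stop("'read' must be a single sequence")
  if (nchar(read) == 0L) stop("empty query")
  if (nchar(read) < params$min_aln_len)
    return(empty_alignments())
  h <- mb_map(index$ptr, read, params$max_seed_gap, params$band_width,
              params$match, params$mismatch, params$gap_open,
              params$gap_extend, params$min_chain_seeds, params$min_aln_len,
              params$max_occ, params$max_ext, params$max_hits,
              params$max_split_hits)
  n <- length(h$target_id)
  out <- data.frame(query_id = rep(query_id, n), query_len = rep(nchar(read), n),
                    query_start = h$query_start, query_end = h$query_end,
                    strand = h$strand, target_id = h$target_id,
                    target_len = unname(index$lengths[h$target_id]),
                    target_start = h$target_start, target_end = h$target_end,
                    matches = h$matches, aln_columns = h$aln_columns,
                    score = h$score, n_seeds = h$n_seeds, cigar = h$cigar,
                    is_primary = h$is_primary, stringsAsFactors = FALSE)
  class(out) <- c("mb_alignments", "data.frame")
  out
}

empty_alignments <- function() {
  out <- data.frame(query_id = character(), query_len = integer(),
                    query_start = integer(), query_end = integer(),
                    strand = character(), target_id = character(),
                    target_len = integer(), target_start = integer(),
                    target_end = integer(), matches = integer(),
                    aln_columns = integer(), score = numeric(),
                    n_seeds = integer(), cigar = character(),
                    is_primary = logical(), stringsAsFactors = FALSE)
  class(out) <- c("mb_alignments", "data.frame")
  out
}

#' Map a set of long reads
#'
#' Vectorised wrapper around [map_long_read()].
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @inheritParams map_long_read
#' @param primary_only keep only the primary record of each read.
#' @return An `mb_alignments` data.frame (all reads concatenated).
#' @export
map_reads <- function(reads, index, params = aligner_params(),
                      primary_only = FALSE) {
  reads <- as_chr_seqs(reads)
  res <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    if (nchar(reads[[i]]) < params$min_aln_len) next
    a <- map_long_read(reads[[i]], index, params, query_id = names(reads)[i])
    if (primary_only && nrow(a)) a <- a[a$is_primary, , drop = FALSE]
    if (nrow(a)) res[[i]] <- a
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_alignments())
  out <- do.call(rbind, res)
  class(out) <- c("mb_alignments", "data.frame")
  rownames(out) <- NULL
  out
}

#' Percent identity of an optimal banded global alignment
#'
#' Identity is defined as `100 * matches / alignment columns`, where columns
#' include gap columns. The function is symmetric in its arguments (the pair is
#' ordered canonically before alignment). If the requested band cannot hold the
#' optimal path the band is widened automatically with a warning.
#'
#' @param a,b DNA sequences (character scalars), non-empty.
#' @param band_slack extra half-bandwidth (bp) beyond the length difference.
#' @param params scoring scheme ([aligner_params()]).
#' @return Percent identity in \[0, 100\].
#' @export
global_identity <- function(a, b, band_slack = 50L, params = aligner_params()) {
  g <- global_alignment(a, b, band_slack, params)
  100 * g$matches / g$columns
}

#' Banded global alignment of two sequences
#'
#' @inheritParams global_identity
#' @return list with score, matches, columns, cigar, identity.
#' @export
global_alignment <- function(a, b, band_slack = 50L, params = aligner_params()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  r <- mb_banded_global(a, b, params$match, params$mismatch, params$gap_open,
                        params$gap_extend, as.integer(band_slack))
  if (isTRUE(r$widened))
    warning("alignment band too narrow; widened automatically")
  cig <- r$cigar
  if (swapped) cig <- cigar_swap_gaps(cig)
  list(score = r$score, matches = r$matches, columns = r$columns,
       cigar = cig, identity = 100 * r$matches / r$columns)
}

# ---- cigar helpers ---------------------------------------------------------

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "") return(data.frame(len = integer(), op = character()))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[=XIDM]", cigar))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

cigar_unparse <- function(ops) {
  if (!nrow(ops)) return("")
  keep <- ops$len > 0
  ops <- ops[keep, , drop = FALSE]
  # merge adjacent identical ops
  if (nrow(ops) > 1) {
    grp <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
    ops <- data.frame(len = as.integer(tapply(ops$len, grp, sum)),
                      op = ops$op[!duplicated(grp)])
  }
  paste0(ops$len, ops$op, collapse = "")
}

# exchange I and D ops (swap query/target roles)
cigar_swap_gaps <- function(cigar) {
  chartr("ID", "DI", cigar)
}

# reverse the op order (walk the alignment from the other end)
cigar_reverse <- function(cigar) {
  ops <- cigar_ops(cigar)
  cigar_unparse(ops[rev(seq_len(nrow(ops))), , drop = FALSE])
}

#' Reverse-complement DNA sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) as.character(mb_revcomp(as.character(x)))

# Re-express an alignment record so that the stated side becomes the pileup
# target. Returns list(tstart, qstart, cigar, qseq) with the cigar walking the
# new target forward. `aln` is one row of mb_alignments; `read` the query
# sequence, `on` one of "target" (default orientation) or "query".
orient_for_pileup <- function(aln, read, on = c("target", "query")) {
  on <- match.arg(on)
  if (on == "target") {
    qseq <- if (aln$strand == "-") revcomp(read) else read
    qstart <- if (aln$strand == "-") aln$query_len - aln$query_end else aln$query_start
    list(tstart = aln$target_start, qstart = qstart, cigar = aln$cigar,
         qseq = qseq)
  } else {
    # pileup onto the original query: swap roles; cigar currently walks the
    # oriented query vs forward target
    cig <- cigar_swap_gaps(aln$cigar)
    if (aln$strand == "-") {
      cig <- cigar_reverse(cig)
      qseq <- revcomp(read)             # 'read' here is the target sequence
      qstart <- nchar(read) - aln$target_end
    } else {
      qseq <- read
      qstart <- aln$target_start
    }
    list(tstart = aln$query_start, qstart = qstart, cigar = cig, qseq = qseq)
  }
}
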