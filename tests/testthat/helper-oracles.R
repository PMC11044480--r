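# Independent oracles used by the tests. These deliberately share no code
# with the package implementation beyond the scoring conventions they state.

# full-matrix (unbanded) global alignment with affine gaps; returns percent
# identity = 100 * matches / columns of one optimal alignment. Plain-R
# dynamic programming with the same tie-break preference (diagonal, then
# gap-in-target, then gap-in-query) as the banded implementation declares.
oracle_global_identity <- function(a, b, match = 1, mismatch = -2,
                                   gap_open = 2, gap_extend = 1) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap consuming b ('D')
  F <- matrix(NEG, n + 1, m + 1)  # gap consuming a ('I')
  M[1, 1] <- 0
  for (j in 2:(m + 1)) E[1, j] <- -(gap_open + gap_extend * (j - 1))
  if (n >= 1) for (i in 2:(n + 1)) F[i, 1] <- -(gap_open + gap_extend * (i - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
      E[i, j] <- max(max(M[i, j - 1], E[i, j - 1], F[i, j - 1]) -
                       gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(max(M[i - 1, j], E[i - 1, j], F[i - 1, j]) -
                       gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
    }
  }
  # traceback counting matches and columns
  i <- n + 1; j <- m + 1
  vals <- c(M[i, j], E[i, j], F[i, j])
  layer <- which.max(vals)
  matches <- 0; columns <- 0
  while (i > 1 || j > 1) {
    if (layer == 1) {
      columns <- columns + 1
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1
      layer <- which.max(c(M[i, j], E[i, j], F[i, j]))
    } else if (layer == 2) {
      columns <- columns + 1
      opened <- max(M[i, j - 1], E[i, j - 1], F[i, j - 1]) -
        gap_open - gap_extend >= E[i, j - 1] - gap_extend
      j <- j - 1
      layer <- if (opened) which.max(c(M[i, j], E[i, j], F[i, j])) else 2
    } else {
      columns <- columns + 1
      opened <- max(M[i - 1, j], E[i - 1, j], F[i - 1, j]) -
        gap_open - gap_extend >= F[i - 1, j] - gap_extend
      i <- i - 1
      layer <- if (opened) which.max(c(M[i, j], E[i, j], F[i, j])) else 3
    }
    if (i == 1 && j == 1) break
  }
  100 * matches / columns
}

# two-sided Fisher exact p-value by brute-force summation of hypergeometric
# probabilities over every table with the observed margins; tables whose
# probability is within relative tolerance of the observed one count as
# "at least as extreme"
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  p <- stats::dhyper(x, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(p[p <= pobs * (1 + 1e-7)])
}

# naive O(reads x elements) largest-overlap read counter
oracle_count_overlaps <- function(prim, ann, min_overlap = 100) {
  counts <- stats::setNames(integer(nrow(ann)), ann$id)
  ann <- ann[order(match(ann$chrom, unique(ann$chrom)), ann$start), ]
  for (r in seq_len(nrow(prim))) {
    best <- NA; bestov <- 0
    for (e in seq_len(nrow(ann))) {
      if (prim$target_id[r] != ann$chrom[e]) next
      ov <- min(prim$target_end[r], ann$end[e]) -
        max(prim$target_start[r], ann$start[e])
      if (ov >= min_overlap && ov > bestov) { bestov <- ov; best <- ann$id[e] }
    }
    if (!is.na(best)) counts[best] <- counts[best] + 1L
  }
  counts
}

# brute-force run scan over a density vector (single chromosome): maximal
# runs of above-threshold windows allowing <= max_gap sub-threshold windows
oracle_run_scan <- function(hot, min_windows = 3, max_gap = 1) {
  runs <- list()
  i <- 1
  n <- length(hot)
  while (i <= n) {
    if (!hot[i]) { i <- i + 1; next }
    start <- i; last <- i; gap <- 0; j <- i + 1
    while (j <= n) {
      if (hot[j]) { last <- j; gap <- 0 } else {
        gap <- gap + 1
        if (gap > max_gap) break
      }
      j <- j + 1
    }
    if (last - start + 1 >= min_windows)
      runs[[length(runs) + 1]] <- c(start, last)
    i <- last + 1
  }
  runs
}

# brute-force six-frame ORF scan via regular expressions on each frame
oracle_longest_orf <- function(seq, min_codons = 1) {
  seq <- toupper(seq)
  best <- 0L
  for (s in c(seq, mobilomeR::revcomp(seq))) {
    for (off in 0:2) {
      body <- substr(s, off + 1, nchar(s))
      ncod <- nchar(body) %/% 3
      if (ncod < 2) next
      cods <- substring(body, 3 * (0:(ncod - 1)) + 1, 3 * (0:(ncod - 1)) + 3)
      txt <- paste(ifelse(cods %in% c("TAA", "TAG", "TGA"), "*",
                          ifelse(cods == "ATG", "M", "x")), collapse = "")
      hits <- regmatches(txt, gregexpr("M[Mx]*\\*", txt))[[1]]
      if (length(hits)) best <- max(best, max(nchar(hits)) - 1L)
    }
  }
  if (best < min_codons) 0L else best
}

# cached default-scenario simulation shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_reference(sim_config(seed = seed))
  .sim_cache[[key]]
}
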