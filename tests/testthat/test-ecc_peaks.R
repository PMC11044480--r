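make_aln <- function(chrom, start, end, id = paste0("r", seq_along(start)),
                     primary = TRUE) {
  n <- length(start)
  data.frame(query_id = id, query_len = 5000L, query_start = 0L,
             query_end = end - start, strand = "+", target_id = chrom,
             target_len = 1000000L, target_start = start, target_end = end,
             matches = end - start, aln_columns = end - start,
             score = end - start, n_seeds = 10L, cigar = NA_character_,
             is_primary = rep(primary, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("reads are counted once, toward the largest-overlap element", {
  ann <- data.frame(id = c("A", "B"), chrom = "chr1",
                    start = c(1000L, 2000L), end = c(1800L, 2800L),
                    stringsAsFactors = FALSE)
  # ten reads fully inside A
  a <- make_aln("chr1", rep(1100L, 10), rep(1700L, 10))
  res <- count_reads_per_element(a, ann)
  expect_equal(unname(res$counts), c(10L, 0L))
  expect_equal(res$unassigned, 0L)
  # read overlapping A by 300 bp and B by 150 bp goes to A only
  b <- make_aln("chr1", 1500L, 2150L)
  res2 <- count_reads_per_element(b, ann, min_overlap = 100)
  expect_equal(unname(res2$counts), c(1L, 0L))
  # below min_overlap the read is unassigned
  c3 <- make_aln("chr1", 1750L, 1950L)
  res3 <- count_reads_per_element(c3, ann, min_overlap = 100)
  expect_equal(sum(res3$counts), 0L)
  expect_equal(res3$unassigned, 1L)
  # unknown chromosome errors
  expect_error(count_reads_per_element(make_aln("chrX", 1L, 500L), ann),
               "unknown chromosome")
})

test_that("counting matches a naive overlap oracle on random placements", {
  set.seed(501)
  ann <- data.frame(id = sprintf("E%02d", 1:30),
                    chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                    start = sample.int(900000, 30), stringsAsFactors = FALSE)
  ann$end <- ann$start + sample(2000:6000, 30, replace = TRUE)
  ann <- ann[order(ann$chrom, ann$start), ]
  ann$id <- sprintf("E%02d", seq_len(nrow(ann)))   # ids follow position
  starts <- sample.int(950000, 1000)
  aln <- make_aln(sample(c("c1", "c2"), 1000, replace = TRUE), starts,
                  starts + sample(200:3000, 1000, replace = TRUE))
  got <- count_reads_per_element(aln, ann, min_overlap = 100)
  exp <- oracle_count_overlaps(aln, ann, min_overlap = 100)
  expect_equal(got$counts, exp)
  # conservation: assigned + unassigned = primary records
  expect_equal(sum(got$counts) + got$unassigned, nrow(aln))
})

test_that("normalisation is per 100,000 library reads", {
  expect_equal(normalize_cpm100k(32, 64000), 50)
  expect_equal(normalize_cpm100k(0, 48000), 0)
  expect_equal(normalize_cpm100k(64000, 64000), 1e5)
  expect_error(normalize_cpm100k(5, 0), "positive")
})

test_that("Fisher p-values equal the brute-force hypergeometric oracle", {
  set.seed(502)
  for (i in 1:200) {
    tot <- sample(50:2000, 2)
    a <- rbinom(1, tot[1], runif(1, 0, 0.1))
    c <- rbinom(1, tot[2], runif(1, 0, 0.1))
    counts_t <- stats::setNames(a, "E1")
    counts_c <- stats::setNames(c, "E1")
    got <- call_differential(counts_t, counts_c, tot, min_reads = 0)$p_value
    exp <- oracle_fisher_p(a, tot[1] - a, c, tot[2] - c)
    expect_lt(abs(got - exp), 1e-10)
  }
  # the paper-style strong case
  got <- call_differential(c(E = 15L), c(E = 1L), c(1000L, 1000L))$p_value
  expect_lt(abs(got - oracle_fisher_p(15, 985, 1, 999)), 1e-10)
})

test_that("differential calling applies thresholds, direction and BH", {
  # symmetric table -> p = 1, low_count under the default read threshold
  r <- call_differential(c(E = 5L), c(E = 5L), c(1000L, 1000L))
  expect_equal(r$p_value, 1)
  expect_equal(r$status, "low_count")
  # 11 combined reads with strong enrichment -> significant
  counts_t <- stats::setNames(c(11L, 5L, 4L), c("hot", "x", "y"))
  counts_c <- stats::setNames(c(0L, 5L, 6L), c("hot", "x", "y"))
  r2 <- call_differential(counts_t, counts_c, c(1000L, 1000L),
                          min_reads = 10, alpha = 0.01)
  hot <- r2[r2$element_id == "hot", ]
  expect_equal(hot$status, "significant")
  expect_lt(hot$p_adj, 0.01)
  expect_gt(hot$cpm100k_treat, hot$cpm100k_ctrl)
  expect_equal(r2$status[r2$element_id == "x"], "low_count")
  # enrichment in the control direction is never "significant"
  r3 <- call_differential(c(E = 0L, F = 30L), c(E = 11L, F = 30L),
                          c(1000L, 1000L))
  expect_equal(r3$status[r3$element_id == "E"], "tested")
  # input validation
  expect_error(call_differential(c(E = -1L), c(E = 0L), c(10L, 10L)), "negative")
  expect_error(call_differential(c(E = 20L), c(E = 0L), c(10L, 10L)), "exceeds")
  expect_error(call_differential(c(E = 1L), c(E = 0L), c(0L, 10L)), "positive")
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(503)
  n <- 40
  counts_t <- stats::setNames(rpois(n, 20), sprintf("E%02d", 1:n))
  counts_c <- stats::setNames(rpois(n, 20), sprintf("E%02d", 1:n))
  counts_t[1] <- 90L
  r <- call_differential(counts_t, counts_c, c(5000L, 5000L))
  tested <- r[r$status != "low_count", ]
  ord <- order(tested$p_value)
  expect_true(all(diff(tested$p_adj[ord]) >= -1e-12))
  expect_true(all(tested$p_adj <= 1))
  expect_true(all(tested$p_adj >= tested$p_value - 1e-12))
  # output sorted by adjusted p then id
  expect_equal(r$element_id[1], "E01")
})

test_that("type-I error is controlled under a null count simulation", {
  # both conditions drawn from one mixture; fraction of significant calls
  # at alpha = 0.01 stays below 0.02 over 50 seeded replicates
  n_elem <- 200
  n_sig <- 0; n_tested <- 0
  for (s in 1:50) {
    set.seed(600 + s)
    mix <- rgamma(n_elem, shape = 2)
    mix <- mix / sum(mix)
    ct <- stats::setNames(as.integer(rmultinom(1, 5000, mix)),
                          sprintf("E%03d", 1:n_elem))
    cc <- stats::setNames(as.integer(rmultinom(1, 5000, mix)),
                          sprintf("E%03d", 1:n_elem))
    r <- call_differential(ct, cc, c(5000L, 5000L), min_reads = 10,
                           alpha = 0.01)
    n_sig <- n_sig + sum(r$status == "significant")
    n_tested <- n_tested + sum(r$status != "low_count")
  }
  expect_lte(n_sig / n_tested, 0.02)
})
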