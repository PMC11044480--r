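test_that("exact reads map back to their origin with identity 100", {
  set.seed(101)
  ref <- stats::setNames(random_dna(30000, 0.4), "chr1")
  idx <- build_reference_index(ref)
  read <- substr(ref, 10001, 12000)
  a <- map_long_read(read, idx)
  prim <- a[a$is_primary, ]
  expect_equal(nrow(prim), 1L)
  expect_equal(prim$target_start, 10000)
  expect_equal(prim$target_end, 12000)
  expect_equal(prim$strand, "+")
  expect_equal(100 * prim$matches / prim$aln_columns, 100)

  b <- map_long_read(revcomp(read), idx)
  bp <- b[b$is_primary, ]
  expect_equal(bp$strand, "-")
  expect_equal(bp$target_start, 10000)
  expect_equal(bp$target_end, 12000)
  expect_equal(bp$matches, 2000L)
})

test_that("map_long_read rejects empty queries and unindexed references", {
  set.seed(102)
  ref <- stats::setNames(random_dna(5000, 0.5), "chr1")
  idx <- build_reference_index(ref)
  expect_error(map_long_read("", idx), "empty query")
  expect_error(map_long_read("ACGTACGT", "not an index"), "index")
})

test_that("tandem copies of a circle yield one record per copy covering it 3x", {
  set.seed(103)
  ref <- stats::setNames(random_dna(30000, 0.45), "chr1")
  idx <- build_reference_index(ref)
  circ <- substr(ref, 5001, 6500)
  read3 <- paste(rep(circ, 3), collapse = "")
  d <- map_long_read(read3, idx)
  same <- d[d$target_start >= 4900 & d$target_end <= 6600, ]
  expect_gte(nrow(same), 3L)
  expect_equal(sum(d$is_primary), 1L)
  # every base of the circle covered three times by the union of records
  cov <- integer(1500)
  for (i in seq_len(nrow(same))) {
    s <- max(same$target_start[i], 5000) - 5000
    e <- min(same$target_end[i], 6500) - 5000
    cov[(s + 1):e] <- cov[(s + 1):e] + 1L
  }
  expect_true(all(cov == 3L))
  # query intervals of the copies are adjacent
  qs <- sort(same$query_start)
  expect_true(all(abs(diff(qs) - 1500) <= 2))
})

test_that("primary record always carries the maximum score", {
  set.seed(104)
  sim <- cached_sim()
  idx <- build_reference_index(sim$genome)
  reads <- simulate_eccdna_reads(sim, "treatment", n_reads = 30)$reads
  for (r in reads[1:15]) {
    a <- map_long_read(r, idx)
    if (!nrow(a)) next
    expect_equal(sum(a$is_primary), 1L)
    expect_true(all(a$score[a$is_primary] >= a$score))
  }
})

test_that("banded global identity matches the full-matrix oracle", {
  set.seed(105)
  for (i in 1:100) {
    len <- sample(80:160, 1)
    a <- random_dna(len, runif(1, 0.3, 0.6))
    nmut <- sample(0:round(0.2 * len), 1)
    b <- mobilomeR:::mutate_subst(a, n = nmut)$seq
    # a few indels as well
    if (runif(1) < 0.5) {
      cut <- sample(len - 10, 1)
      b <- paste0(substr(b, 1, cut), random_dna(sample(1:4, 1), 0.5),
                  substr(b, cut + 1, nchar(b)))
    }
    got <- global_identity(a, b, band_slack = 50)
    exp <- oracle_global_identity(a, b)
    expect_lt(abs(got - exp), 0.1)
  }
})

test_that("global identity is symmetric, 100 on self, and counts gap columns", {
  set.seed(106)
  for (i in 1:20) {
    a <- random_dna(sample(100:400, 1), 0.5)
    b <- mobilomeR:::mutate_subst(a, n = sample(0:30, 1))$seq
    expect_identical(global_identity(a, b), global_identity(b, a))
    expect_equal(global_identity(a, a), 100)
  }
  # 10 substitutions in 500 bp -> exactly 98.0
  a <- random_dna(500, 0.5)
  b <- mobilomeR:::mutate_subst(a, n = 10)$seq
  expect_equal(global_identity(a, b), 98)
  # a deletion adds gap columns to the denominator
  d <- paste0(substr(a, 1, 200), substr(a, 251, 500))
  expect_equal(global_identity(a, d), 100 * 450 / 500)
  expect_error(global_identity("", a), "empty")
})

test_that("noisy 2 kb reads are recovered within 20 bp at both ends", {
  set.seed(107)
  ref <- stats::setNames(random_dna(700000, 0.4), "chr1")
  idx <- build_reference_index(ref)
  n <- 200
  starts <- sample(1:(700000 - 2000), n)
  reads <- vapply(starts, function(s) substr(ref, s, s + 1999), character(1))
  reads <- as.character(mobilomeR:::mb_corrupt(reads, 0.05, 0.025, 0.025))
  names(reads) <- paste0("r", seq_len(n))
  aln <- map_reads(reads, idx, aligner_params(max_hits = 1), primary_only = TRUE)
  truth <- starts[match(aln$query_id, names(reads))] - 1
  ok <- abs(aln$target_start - truth) <= 20 & abs(aln$target_end - (truth + 2000)) <= 20
  expect_gte(sum(ok) / n, 0.95)
})

test_that("PAF round-trip preserves alignment records", {
  set.seed(108)
  ref <- stats::setNames(random_dna(20000, 0.5), "chrZ")
  idx <- build_reference_index(ref)
  reads <- c(r1 = substr(ref, 2001, 3500), r2 = revcomp(substr(ref, 9001, 11000)))
  aln <- map_reads(reads, idx)
  path <- withr::local_tempfile(fileext = ".paf")
  write_paf(aln, path)
  back <- read_paf(path)
  expect_equal(back$query_id, aln$query_id)
  expect_equal(back$target_start, aln$target_start)
  expect_equal(back$target_end, aln$target_end)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$matches, aln$matches)
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$is_primary, aln$is_primary)
})
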