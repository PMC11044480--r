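test_that("planted LTR pairs are detected with oracle-consistent identity", {
  set.seed(401)
  host <- random_dna(60000, 0.4)
  ltr <- random_dna(500, 0.4)
  elem <- paste0(ltr, random_dna(4000, 0.4), ltr)
  ltr2 <- random_dna(450, 0.4)
  ltr2b <- mobilomeR:::mutate_subst(ltr2, n = 9)$seq   # ~2% diverged pair
  elem2 <- paste0(ltr2, random_dna(3500, 0.4), ltr2b)
  gen <- stats::setNames(paste0(substr(host, 1, 20000), elem,
                                substr(host, 20001, 40000), elem2,
                                substr(host, 40001, 60000)), "chrA")
  det <- detect_ltr_pairs(gen)
  expect_equal(nrow(det), 2L)
  d1 <- det[which.min(abs(det$start - 20000)), ]
  expect_equal(d1$ltr_identity, 100)
  expect_lt(abs(d1$start - 20000), 20)
  expect_lt(abs(d1$end - 25000), 20)
  d2 <- det[which.min(abs(det$start - 45000)), ]
  # reported identity close to the oracle value for the planted pair
  exp_id <- oracle_global_identity(ltr2, ltr2b)
  expect_lt(abs(d2$ltr_identity - exp_id), 0.5)
  # no intervals overlap after resolution
  det <- det[order(det$start), ]
  if (nrow(det) > 1)
    expect_true(all(det$start[-1] >= det$end[-nrow(det)]))
})

test_that("a repeat-free genome yields no LTR pairs", {
  set.seed(402)
  gen <- stats::setNames(random_dna(30000, 0.45), "chr")
  expect_equal(nrow(detect_ltr_pairs(gen)), 0L)
})

test_that("family clustering recovers the planted families", {
  sim <- cached_sim()
  ltrs <- ltr5_sequences(sim$genome, sim$annotation)
  cl <- cluster_families(ltrs, linkage_threshold = 80)
  truth <- sim$annotation$family
  got <- unname(cl$family[sim$annotation$id])
  # same partition: families map one-to-one
  expect_equal(length(unique(got)), length(unique(truth)))
  tab <- table(truth, got)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # neighbour-joining companion tree covers every element
  expect_s3_class(cl$tree, "phylo")
  expect_setequal(cl$tree$tip.label, sim$annotation$id)
})

test_that("family clustering edge cases behave as specified", {
  set.seed(403)
  one <- c(el1 = random_dna(400, 0.5))
  expect_equal(unname(cluster_families(one)$family), "FAM1")
  three <- c(a = random_dna(400, 0.5), b = random_dna(400, 0.5),
             c = random_dna(400, 0.5))
  # threshold above 100 leaves every element in its own family
  cl <- cluster_families(three, linkage_threshold = 101)
  expect_equal(length(unique(cl$family)), 3L)
})

test_that("cluster count never increases when the threshold is lowered", {
  sim <- cached_sim()
  set.seed(404)
  ids <- sample(sim$annotation$id, 12)
  ltrs <- ltr5_sequences(sim$genome,
                         sim$annotation[sim$annotation$id %in% ids, ])
  n_prev <- Inf
  for (thr in c(101, 95, 90, 80, 60, 40, 0)) {
    n <- length(unique(cluster_families(ltrs, linkage_threshold = thr)$family))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_equal(n_prev, 1L)
})

test_that("ORF scan matches a brute-force six-frame oracle", {
  set.seed(405)
  for (i in 1:100) {
    s <- random_dna(sample(120:900, 1), runif(1, 0.3, 0.6))
    got <- scan_orfs(s, min_codons = 5)
    expect_equal(if (nrow(got)) got$codons[1] else 0L,
                 oracle_longest_orf(s, min_codons = 5))
  }
  # minimal case
  expect_equal(scan_orfs("ATGTAA", min_codons = 1)$codons, 1L)
  expect_error(scan_orfs("ATG%%%"), "non-IUPAC")
})

test_that("catalogue table combines identity, family and longest ORF", {
  sim <- cached_sim()
  sub <- sim$annotation[sim$annotation$id %in% sim$truth$active_elements, ]
  cat_res <- te_catalog(sim$genome, sub, min_codons = 300)
  expect_equal(nrow(cat_res$catalog), 2L)
  # master copies have identical LTRs and the planted reading frames
  expect_true(all(cat_res$catalog$ltr_identity == 100))
  expect_setequal(cat_res$catalog$longest_orf_codons, c(1302L, 1173L))
})
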