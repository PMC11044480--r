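test_that("sim_config validates its inputs", {
  expect_error(sim_config(ecc_mix = c(solo_LTR = 0.5, full_1LTR = 0.4)), "sum to 1")
  expect_error(sim_config(ecc_mix = c(weird = 1)), "structure class")
  expect_error(sim_config(tsd_len = 9), "tsd_len")
  expect_error(sim_config(error_rates = c(sub = 0.6, ins = 0.3, del = 0.2)), "error rates")
  expect_error(sim_config(active_families = 9), "out of range")
})

test_that("simulated reference plants the configured elements with TSDs", {
  sim <- cached_sim()
  cfg <- sim$truth$config
  ann <- sim$annotation
  expect_equal(nrow(ann), cfg$n_families * cfg$copies_per_family)
  expect_equal(length(sim$truth$active_elements), length(cfg$active_families))
  # element lengths within LTR/internal bounds
  lens <- ann$end - ann$start
  expect_true(all(lens >= 2 * cfg$ltr_len_range[1] + cfg$internal_len_range[1]))
  # TSD flanks the insertion: the recorded site is duplicated on both sides
  for (i in sample(nrow(ann), 5)) {
    g <- sim$genome[[ann$chrom[i]]]
    left <- substr(g, ann$start[i] - cfg$tsd_len + 1, ann$start[i])
    right <- substr(g, ann$end[i] + 1, ann$end[i] + cfg$tsd_len)
    expect_equal(left, ann$tsd[i])
    expect_equal(right, ann$tsd[i])
  }
  # extracted element sequences match the recorded truth
  for (id in sample(ann$id, 5))
    expect_equal(element_sequence(sim, id), sim$truth$element_seqs[[id]])
})

test_that("reference simulation is byte-identical under a fixed seed", {
  s1 <- simulate_reference(sim_config(seed = 99))
  s2 <- simulate_reference(sim_config(seed = 99))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$donor_templates, s2$truth$donor_templates)
  r1 <- simulate_eccdna_reads(s1, "treatment", n_reads = 50)
  r2 <- simulate_eccdna_reads(s2, "treatment", n_reads = 50)
  expect_identical(r1$reads, r2$reads)
  w1 <- simulate_wgs_reads(s1)
  w2 <- simulate_wgs_reads(s2)
  expect_identical(w1$reads, w2$reads)
  expect_identical(w1$variants, w2$variants)
})

test_that("planted ORFs are recovered from the emitted elements", {
  sim <- cached_sim()
  # the intact master copies carry the planted frames (1302 codons for
  # family 1; 352 + 1173 for family 2); diverged copies may not
  f1 <- sim$annotation$id[sim$annotation$family == "FAM1" &
                            sim$annotation$master][1]
  o1 <- scan_orfs(element_sequence(sim, f1), min_codons = 300)
  expect_equal(o1$codons[1], 1302L)
  f2 <- sim$annotation$id[sim$annotation$family == "FAM2" &
                            sim$annotation$master][1]
  o2 <- scan_orfs(element_sequence(sim, f2), min_codons = 300)
  expect_true(all(c(352L, 1173L) %in% o2$codons))
})

test_that("eccDNA reads follow the configured structure mix and circle law", {
  sim <- cached_sim()
  set.seed(301)
  # pure full_1LTR mix -> every per-read truth class is full_1LTR
  cfg1 <- sim_config(seed = 7, ecc_mix = c(solo_LTR = 0, full_1LTR = 1,
                                           full_2LTR = 0, truncated = 0))
  sim1 <- sim
  sim1$truth$config <- cfg1
  ecc <- simulate_eccdna_reads(sim1, "control", n_reads = 100)
  expect_true(all(ecc$read_truth$class == "full_1LTR"))
  expect_equal(length(ecc$reads), 100L)

  # error-free read of a 1000 bp circle at length 3400 is a rotation
  # repeated 3.4 times
  circ <- substr(sim$genome[[1]], 50001, 51000)
  set.seed(5)
  r <- mobilomeR:::rca_read(circ, 3400)
  expect_equal(nchar(r), 3400L)
  dbl <- paste(rep(circ, 5), collapse = "")
  expect_true(grepl(r, dbl, fixed = TRUE))
  expect_error(build_circle(paste(rep("A", 120), collapse = ""), 40,
                            "solo_LTR"), "50 bp")
})

test_that("read corruption matches the configured error magnitude", {
  sim <- cached_sim()
  # an error-free run with the same seed yields the exact templates of the
  # same reads; edit distance measured with a Levenshtein oracle (utils::adist)
  ecc <- simulate_eccdna_reads(sim, "control", n_reads = 200, seed = 303)
  clean <- simulate_eccdna_reads(sim, "control", n_reads = 200, seed = 303,
                                 error_rates = c(sub = 0, ins = 0, del = 0))
  expect_identical(ecc$read_truth, clean$read_truth)
  set.seed(304)
  sub <- sample(200, 60)
  dist <- mapply(function(x, y) utils::adist(x, y),
                 ecc$reads[sub], clean$reads[sub])
  rate <- sum(dist) / sum(nchar(clean$reads[sub]))
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("WGS simulation honours depth, SNP rates and insertion structure", {
  sim <- cached_sim()
  cfg <- sim$truth$config
  wgs <- simulate_wgs_reads(sim)
  mean_len <- exp(cfg$wgs_len_meanlog + cfg$wgs_len_sdlog^2 / 2)
  expected_n <- round(cfg$wgs_depth * sum(nchar(sim$genome)) / mean_len)
  expect_lt(abs(length(wgs$reads) - expected_n) / expected_n, 0.1)

  # SNP counts: binomial check inside and outside the introgressed segment
  seg <- cfg$introgression
  inseg <- wgs$variants$chrom == seg$chrom & wgs$variants$pos >= seg$start &
    wgs$variants$pos < seg$end
  slen <- seg$end - seg$start
  exp_in <- slen * cfg$background_snp_rate * seg$fold
  sd_in <- sqrt(exp_in)
  expect_lt(abs(sum(inseg) - exp_in), 4 * sd_in)
  gen_len <- sum(nchar(sim$genome))
  exp_out <- (gen_len - slen) * cfg$background_snp_rate
  expect_lt(abs(sum(!inseg) - exp_out), 4 * sqrt(exp_out))

  # error-free reads spanning a planted insertion contain the element
  # flanked by the duplicated target site
  wgs0 <- simulate_wgs_reads(sim, error_rates = c(sub = 0, ins = 0, del = 0))
  ins <- wgs0$insertions[1, ]
  g <- sim$genome[[ins$chrom]]
  tsd <- substr(g, ins$pos + 1, ins$pos + ins$tsd_len)
  eseq <- sim$truth$insertions$seq[1]
  junction <- paste0(substr(g, ins$pos - 50 + 1, ins$pos + ins$tsd_len),
                     substr(eseq, 1, 50))
  found <- any(vapply(wgs0$reads, function(r)
    grepl(junction, r, fixed = TRUE) || grepl(revcomp(junction), r, fixed = TRUE),
    logical(1)))
  expect_true(found)
})

test_that("insertion positions inside annotated elements are rejected", {
  sim <- cached_sim()
  a <- sim$annotation[1, ]
  bad <- data.frame(family = "FAM1", chrom = a$chrom,
                    pos = a$start + 100L, tsd_len = 5L,
                    stringsAsFactors = FALSE)
  expect_error(simulate_reference(sim_config(seed = 7, insertions = bad)),
               "inside an annotated element")
})

test_that("variant-level SNP landscape reproduces the configured rates", {
  v <- simulate_snp_landscape(c(chrA = 5e6), rate = 1e-4,
                              introgression = list(chrom = "chrA",
                                                   start = 1e6, end = 2e6,
                                                   fold = 10),
                              seed = 11)
  inseg <- v$pos >= 1e6 & v$pos < 2e6
  expect_lt(abs(sum(inseg) - 1000) / 1000, 0.2)
  expect_lt(abs(sum(!inseg) - 400) / 400, 0.3)
  # deterministic
  v2 <- simulate_snp_landscape(c(chrA = 5e6), rate = 1e-4,
                               introgression = list(chrom = "chrA",
                                                    start = 1e6, end = 2e6,
                                                    fold = 10),
                               seed = 11)
  expect_identical(v, v2)
})
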