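# a small dedicated scenario keeps the WGS tests fast
wgs_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_reference(sim_config(
        seed = 19, chrom_lengths = c(chr1 = 150000L, chr2 = 100000L),
        n_families = 2L, copies_per_family = 3L,
        introgression = list(chrom = "chr1", start = 40000L, end = 90000L,
                             fold = 20),
        background_snp_rate = 5e-4, n_insertions = 2L, wgs_depth = 15))
    cache
  }
})

test_that("naive pileup calling finds planted SNPs and nothing else", {
  sim <- wgs_sim()
  idx <- build_reference_index(sim$genome)
  wgs0 <- simulate_wgs_reads(sim, error_rates = c(sub = 0, ins = 0, del = 0))
  aln0 <- map_reads(wgs0$reads, idx, aligner_params(max_hits = 4))
  snps0 <- call_snps_naive(aln0, wgs0$reads, sim$genome)
  key <- function(ch, p) paste(ch, p)
  truth <- key(wgs0$variants$chrom, wgs0$variants$pos)
  got <- key(snps0$chrom, snps0$pos)
  covered <- truth %in% got
  expect_gt(mean(covered), 0.97)          # misses only depth gaps
  expect_gt(mean(got %in% truth), 0.99)   # essentially no false calls
  # haploid donor: allele fractions are essentially 1 outside repeat copies
  expect_equal(stats::median(snps0$af), 1)
  expect_gt(mean(snps0$af >= 0.95), 0.98)

  # with substitution noise precision and recall stay >= 0.95
  wgs1 <- simulate_wgs_reads(sim, error_rates = c(sub = 0.05, ins = 0, del = 0))
  aln1 <- map_reads(wgs1$reads, idx, aligner_params(max_hits = 4))
  snps1 <- call_snps_naive(aln1, wgs1$reads, sim$genome)
  got1 <- key(snps1$chrom, snps1$pos)
  expect_gte(mean(truth %in% got1), 0.95)
  expect_gte(mean(got1 %in% truth), 0.95)
})

test_that("density windows tile chromosomes and conserve variant counts", {
  v <- data.frame(chrom = "c1", pos = c(5L, 10L, 999999L, 1000000L, 2500000L))
  tr <- snp_density_windows(v, c(c1 = 2600000), window_size = 1e6)
  w <- tr$windows
  expect_equal(w$count, c(3L, 1L, 1L))
  expect_equal(w$density[1], 3)
  # partial last window density scaled by true width
  expect_equal(w$density[3], 1 * 1e6 / 600000)
  expect_equal(sum(w$count), nrow(v))
  expect_error(snp_density_windows(data.frame(chrom = "c1", pos = 3000000L),
                                   c(c1 = 2600000)), "beyond chromosome")
  # empty input gives zero densities and median 0
  tr0 <- snp_density_windows(v[0, ], c(c1 = 2600000))
  expect_true(all(tr0$windows$count == 0))
  expect_equal(tr0$genome_median, 0)
})

test_that("uniform SNP rates give Poisson-consistent window densities", {
  v <- simulate_snp_landscape(c(cA = 2e7), rate = 1e-4, seed = 21)
  tr <- snp_density_windows(v, c(cA = 2e7), window_size = 1e6)
  expect_true(all(abs(tr$windows$count - 100) <= 4 * sqrt(100)))
  expect_equal(sum(tr$windows$count), nrow(v))
})

test_that("introgression segmentation matches the brute-force run scan", {
  set.seed(802)
  for (i in 1:25) {
    n <- 40
    dens <- rpois(n, 5)
    hot_idx <- sample(n, sample(3:12, 1))
    dens[hot_idx] <- dens[hot_idx] + 200
    w <- data.frame(chrom = "c", win_start = (0:(n - 1)) * 1e6,
                    win_end = (1:n) * 1e6, count = dens, density = dens,
                    full = TRUE)
    track <- structure(list(windows = w, window_size = 1e6,
                            genome_median = stats::median(dens)),
                       class = "snp_density")
    thr <- 5 * stats::median(dens)
    got <- segment_introgressions(track, fold_threshold = 5, min_windows = 3,
                                  max_gap = 1)
    exp <- oracle_run_scan(dens >= thr, min_windows = 3, max_gap = 1)
    expect_equal(nrow(got), length(exp))
    for (k in seq_along(exp)) {
      expect_equal(got$start[k], (exp[[k]][1] - 1) * 1e6)
      expect_equal(got$end[k], exp[[k]][2] * 1e6)
    }
  }
})

test_that("segmentation is order-invariant, gap-aware and warns on zero median", {
  dens <- c(rep(2, 10), 60, 60, 2, 60, 60, rep(2, 10), 60, 60, 60, rep(2, 7))
  n <- length(dens)
  w <- data.frame(chrom = "c", win_start = (0:(n - 1)) * 1e6,
                  win_end = (1:n) * 1e6, count = dens, density = dens,
                  full = TRUE)
  track <- structure(list(windows = w, window_size = 1e6, genome_median = 2),
                     class = "snp_density")
  segs <- segment_introgressions(track, fold_threshold = 5, min_windows = 3,
                                 max_gap = 1)
  # one bridged run of 5 windows, one run of 3; separated by > max_gap
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_windows, c(5L, 3L))
  # shuffled window rows give identical output
  track2 <- track
  track2$windows <- track2$windows[sample(n), ]
  expect_equal(segment_introgressions(track2, 5, 3, 1), segs)
  # uniform density -> nothing
  w0 <- w; w0$density <- 3; w0$count <- 3L
  track0 <- structure(list(windows = w0, window_size = 1e6, genome_median = 3),
                      class = "snp_density")
  expect_equal(nrow(segment_introgressions(track0, 5, 3, 1)), 0L)
  # zero median falls back to the absolute threshold with a warning
  trackz <- structure(list(windows = w, window_size = 1e6, genome_median = 0),
                      class = "snp_density")
  expect_warning(segment_introgressions(trackz, 5, 3, 1), "absolute threshold")
})

test_that("planted high-SNP segments are recovered within one window", {
  for (s in 1:5) {
    v <- simulate_snp_landscape(c(cA = 5e7), rate = 1e-4,
                                introgression = list(chrom = "cA",
                                                     start = 2e7, end = 3e7,
                                                     fold = 20), seed = s)
    tr <- snp_density_windows(v, c(cA = 5e7), window_size = 1e6)
    segs <- segment_introgressions(tr, fold_threshold = 5, min_windows = 3)
    expect_equal(nrow(segs), 1L)
    expect_lte(abs(segs$start - 2e7), 1e6)
    expect_lte(abs(segs$end - 3e7), 1e6)
  }
})

test_that("TEIs are called exactly on error-free reads", {
  sim <- wgs_sim()
  idx <- build_reference_index(sim$genome)
  lib <- stats::setNames(vapply(sim$truth$families, `[[`, character(1),
                                "consensus"), names(sim$truth$families))
  wgs0 <- simulate_wgs_reads(sim, error_rates = c(sub = 0, ins = 0, del = 0))
  aln0 <- map_reads(wgs0$reads, idx, aligner_params(max_hits = 4))
  teis <- call_teis(aln0, wgs0$reads, lib, sim$genome)
  truth <- sim$truth$insertions
  expect_equal(nrow(teis), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- teis[teis$chrom == truth$chrom[i] &
                  teis$position == truth$pos[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$family, truth$family[i])
    expect_equal(nchar(hit$tsd), 5L)
    g <- sim$genome[[truth$chrom[i]]]
    expect_equal(hit$tsd, substr(g, truth$pos[i] + 1, truth$pos[i] + 5))
  }
})

test_that("insertions below min_support are not called", {
  sim <- wgs_sim()
  truth <- sim$truth$insertions[1, ]
  lib <- stats::setNames(vapply(sim$truth$families, `[[`, character(1),
                                "consensus"), names(sim$truth$families))
  # construct two synthetic spanning reads' worth of split evidence
  mk_pair <- function(rid) {
    data.frame(query_id = rid, query_len = 9000L,
               query_start = c(0L, 6500L), query_end = c(2000L, 9000L),
               strand = "+", target_id = truth$chrom, target_len = 150000L,
               target_start = c(truth$pos - 2000L + 5L, truth$pos),
               target_end = c(truth$pos + 5L, truth$pos + 2500L),
               matches = c(2000L, 2500L), aln_columns = c(2000L, 2500L),
               score = c(2000, 2500), n_seeds = 10L, cigar = NA_character_,
               is_primary = c(TRUE, FALSE), stringsAsFactors = FALSE)
  }
  aln <- rbind(mk_pair("ra"), mk_pair("rb"))
  g <- sim$genome[[truth$chrom]]
  reads <- stats::setNames(rep(paste0(
    substr(g, truth$pos - 2000 + 1 + 5, truth$pos + 5),
    truth$seq, substr(g, truth$pos + 1, truth$pos + 2500)), 2), c("ra", "rb"))
  got2 <- call_teis(aln, reads, lib, sim$genome, min_support = 3)
  expect_equal(nrow(got2), 0L)
  got3 <- call_teis(aln, reads, lib, sim$genome, min_support = 2)
  expect_equal(nrow(got3), 1L)
})

test_that("flank check distinguishes occupied and empty sites", {
  sim <- wgs_sim()
  el <- sim$annotation[1, ]
  # an assembly carrying the same locus with the element
  other_full <- sim$genome
  res1 <- flank_check(sim$genome, el, other_full)
  expect_true(res1$locus_present)
  # an assembly with the element excised (flanks joined)
  g <- sim$genome[[el$chrom]]
  excised <- stats::setNames(paste0(substr(g, 1, el$start),
                                    substr(g, el$end + 1, nchar(g))), "alt")
  res2 <- flank_check(sim$genome, el, excised)
  expect_false(res2$locus_present)
  expect_true(res2$empty_site_present)
})
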