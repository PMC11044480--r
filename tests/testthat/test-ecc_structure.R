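active_element <- function(sim, which = 1) {
  id <- sim$truth$active_elements[which]
  ann <- sim$annotation[sim$annotation$id == id, ]
  list(id = id, ann = ann, seq = sim$truth$element_seqs[[id]],
       donor = sim$truth$donor_templates[[id]],
       ltr_len = sim$truth$families[[ann$family]]$ltr_len,
       sites = sim$truth$divergent_sites[[id]])
}

test_that("error-free concatemers decompose to the exact circle length", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(701)
  # a 1,000 bp circle read 3.4 times over
  circ <- substr(el$seq, 1, 1000)
  r <- mobilomeR:::rca_read(circ, 3400)
  d <- decompose_concatemer(r, circ, element_id = el$id)
  expect_equal(d$monomer_len, 1000)
  expect_equal(d$n_full_monomers, 3L)
  # all structural classes, all phases
  for (rep in 1:8) for (cl in c("solo_LTR", "full_1LTR", "full_2LTR",
                                "truncated")) {
    circ <- build_circle(el$seq, el$ltr_len, cl)
    r <- mobilomeR:::rca_read(circ, round(runif(1, 2.2, 4) * nchar(circ)))
    d <- decompose_concatemer(r, el$seq, element_id = el$id)
    expect_equal(d$monomer_len, nchar(circ))
  }
  expect_error(decompose_concatemer(r, ""), "empty")
})

test_that("reads without hits give an empty decomposition, not an error", {
  set.seed(702)
  d <- decompose_concatemer(random_dna(1500, 0.5), random_dna(800, 0.5))
  expect_equal(d$n_full_monomers, 0L)
  expect_equal(d$consensus, "")
  expect_true(is.na(d$monomer_len))
})

test_that("fewer than two full monomers leave the consensus empty", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(703)
  circ <- build_circle(el$seq, el$ltr_len, "full_2LTR")
  r <- mobilomeR:::rca_read(circ, round(1.4 * nchar(circ)))
  d <- decompose_concatemer(r, el$seq, element_id = el$id)
  expect_lt(d$n_full_monomers, 2L)
  expect_equal(d$consensus, "")
})

test_that("structure classification covers every rule branch", {
  sim <- cached_sim()
  for (w in 1:2) {
    el <- active_element(sim, w)
    set.seed(710 + w)
    cases <- expand.grid(cl = c("solo_LTR", "full_1LTR", "full_2LTR",
                                "truncated"), rep = 1:6,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cases))) {
      cl <- cases$cl[i]
      circ <- build_circle(el$seq, el$ltr_len, cl)
      r <- mobilomeR:::rca_read(circ, round(runif(1, 2.3, 4) * nchar(circ)))
      d <- decompose_concatemer(r, el$seq, element_id = el$id)
      call <- classify_structure(d, el$ann)
      expect_equal(call$class, cl)
    }
    # internal-only circle: full coverage but no LTR copy -> "other"
    circ <- build_circle(el$seq, el$ltr_len, "full_2LTR", drop_ltr = TRUE)
    r <- mobilomeR:::rca_read(circ, round(2.5 * nchar(circ)))
    d <- decompose_concatemer(r, el$seq, element_id = el$id)
    expect_equal(classify_structure(d, el$ann)$class, "other")
  }
  # missing LTR sub-intervals error
  el <- active_element(sim)
  circ <- build_circle(el$seq, el$ltr_len, "full_1LTR")
  d <- decompose_concatemer(mobilomeR:::rca_read(circ, 8000), el$seq)
  expect_error(classify_structure(d, list(ltr5_start = NA)), "LTR sub-intervals")
})

test_that("a planted internal deletion is reported at its exact size", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(720)
  circ <- build_circle(el$seq, el$ltr_len, "full_1LTR",
                       internal_deletion = c(2000, 25))
  r <- mobilomeR:::rca_read(circ, round(2.6 * nchar(circ)))
  d <- decompose_concatemer(r, el$seq, element_id = el$id)
  call <- classify_structure(d, el$ann)
  expect_equal(call$class, "full_1LTR")
  expect_equal(nrow(call$deletions), 1L)
  expect_equal(call$deletions$end - call$deletions$start, 25)
  expect_equal(call$deletions$start, el$ltr_len + 2000)
})

test_that("planted substitutions are recovered exactly from clean pileups", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(730)
  ds <- lapply(1:25, function(i) {
    circ <- build_circle(el$donor, el$ltr_len, "full_2LTR")
    r <- mobilomeR:::rca_read(circ, round(2.6 * nchar(circ)))
    decompose_concatemer(r, el$seq, read_id = paste0("r", i),
                         element_id = el$id)
  })
  rep <- consensus_divergence(ds, el$seq, el$ann)
  expect_equal(rep$snp_count, length(el$sites))
  expect_equal(sort(rep$snp_positions), sort(el$sites))
  expect_true(rep$ltr_covered)
  expect_null(rep$ltr_deletion)
})

test_that("LTR coverage and deletion flags raise exactly when constructed", {
  sim <- cached_sim()
  el <- active_element(sim, 2)
  set.seed(731)
  # circles without any LTR sequence
  ds <- lapply(1:12, function(i) {
    circ <- build_circle(el$donor, el$ltr_len, "full_2LTR", drop_ltr = TRUE)
    decompose_concatemer(mobilomeR:::rca_read(circ, round(2.6 * nchar(circ))),
                         el$seq, element_id = el$id)
  })
  rep1 <- consensus_divergence(ds, el$seq, el$ann)
  expect_false(rep1$ltr_covered)
  # circles whose LTR lacks a 24 bp block
  ds2 <- lapply(1:12, function(i) {
    circ <- build_circle(el$donor, el$ltr_len, "full_2LTR",
                         ltr_deletion = c(150, 24))
    decompose_concatemer(mobilomeR:::rca_read(circ, round(2.6 * nchar(circ))),
                         el$seq, element_id = el$id)
  })
  rep2 <- consensus_divergence(ds2, el$seq, el$ann)
  expect_true(rep2$ltr_covered)
  expect_false(is.null(rep2$ltr_deletion))
  expect_equal(rep2$ltr_deletion[2] - rep2$ltr_deletion[1], 24)
})

test_that("origin assignment prefers the least diverged panel genome", {
  sim <- cached_sim()
  el <- active_element(sim)
  qltr <- substr(el$donor, 1, el$ltr_len)
  set.seed(740)
  # query planted verbatim in one genome only
  panel0 <- list(P = stats::setNames(paste0(random_dna(20000, 0.4), qltr,
                                            random_dna(20000, 0.4)), "P_1"),
                 Q = stats::setNames(random_dna(40000, 0.4), "Q_1"))
  oc0 <- assign_origin(qltr, panel0)
  expect_equal(oc0$assigned, "P")
  expect_equal(oc0$per_genome$best_identity[oc0$per_genome$genome == "P"], 100)

  # 2% vs 8% vs 20% divergence -> the 2% genome wins with oracle-close identity
  panel <- simulate_relative_panel(sim, c(SP = 0.02, SC = 0.08, SH = 0.20))
  oc <- assign_origin(qltr, panel)
  expect_equal(oc$assigned, "SP")

  # below the identity floor the call is ambiguous
  far <- mobilomeR:::mutate_subst(qltr, n = round(0.06 * nchar(qltr)))$seq
  panel2 <- list(P = stats::setNames(paste0(random_dna(5000, 0.4), far,
                                            random_dna(5000, 0.4)), "P_1"))
  oc2 <- assign_origin(qltr, panel2, identity_floor = 96)
  expect_equal(oc2$assigned, "ambiguous")
  expect_error(assign_origin(qltr, list()), "empty")
})

test_that("reference-free periodicity recovers the circle length", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(750)
  circ <- build_circle(el$seq, el$ltr_len, "full_1LTR")
  r <- mobilomeR:::rca_read(circ, round(3.2 * nchar(circ)))
  p <- estimate_circle_period(r)
  expect_lt(abs(p - nchar(circ)) / nchar(circ), 0.02)
})

test_that("dot-plot coordinates follow the concatemer diagonal structure", {
  sim <- cached_sim()
  el <- active_element(sim)
  set.seed(760)
  circ <- build_circle(el$seq, el$ltr_len, "full_2LTR")
  r <- mobilomeR:::rca_read(circ, round(2.5 * nchar(circ)))
  d <- decompose_concatemer(r, el$seq, element_id = el$id)
  xy <- monomer_dotplot_coords(d)
  expect_gt(nrow(xy), 2 * nchar(circ))
  # aligned base pairs match between read and element (error-free)
  idx <- sample(nrow(xy), 200)
  rb <- substring(r, xy$read_pos[idx] + 1, xy$read_pos[idx] + 1)
  eb <- substring(el$seq, xy$element_pos[idx] + 1, xy$element_pos[idx] + 1)
  expect_gt(mean(rb == eb), 0.99)
})
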