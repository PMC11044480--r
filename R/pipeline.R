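#' Pipeline run configuration
#'
#' Assembles all stage parameters with their defaults. Unknown keys are
#' rejected. The effective configuration is echoed into the run log and
#' written next to the outputs.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the whole run.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param ... stage parameter overrides: min_overlap, min_reads, alpha,
#'   correction, window_size, fold_threshold, min_windows, max_gap,
#'   min_insert, min_support, cluster_radius, identity_floor, min_margin,
#'   linkage_threshold, structure_top, structure_reads, panel_divergence,
#'   verbose.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "mobilome_run", seed = 1L, sim = NULL, ...) {
  defaults <- list(
    min_overlap = 100L, min_reads = 10L, alpha = 0.01, correction = "BH",
    window_size = 10000L, fold_threshold = 5, min_windows = 3L, max_gap = 1L,
    min_insert = 500L, min_support = 3L, cluster_radius = 50L,
    identity_floor = 96, min_margin = 1.0, linkage_threshold = 80,
    structure_top = 2L, structure_reads = 200L,
    panel_divergence = c(SP = 0.02, SC = 0.08, SH = 0.20),
    verbose = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  else sim$seed <- cfg$seed
  cfg$sim <- sim
  structure(cfg, class = "run_config")
}

#' Simulate a panel of relative-species genome assemblies
#'
#' For origin assignment at desk scale: each panel genome is a random backbone
#' carrying a copy of every active element's donor allele mutated to the given
#' divergence, so exactly one panel genome (the least diverged) is the true
#' origin of the eccDNA consensus sequences.
#'
#' @param sim a `mobilome_sim`.
#' @param divergence named numeric vector: genome name -> per-base divergence
#'   from the donor alleles.
#' @param backbone_len random backbone length per genome (bp).
#' @return named list: genome name -> named character vector.
#' @export
simulate_relative_panel <- function(sim, divergence = c(SP = 0.02, SC = 0.08,
                                                        SH = 0.20),
                                    backbone_len = 50000L) {
  panel <- list()
  for (g in names(divergence)) {
    parts <- character(0)
    for (id in sim$truth$active_elements) {
      donor <- sim$truth$donor_templates[[id]]
      mut <- mutate_subst(donor, n = round(divergence[[g]] * nchar(donor)))
      parts <- c(parts, random_dna(round(backbone_len / 2)), mut$seq)
    }
    parts <- c(parts, random_dna(round(backbone_len / 2)))
    panel[[g]] <- stats::setNames(paste(parts, collapse = ""),
                                  paste0(g, "_chr1"))
  }
  panel
}

log_msg <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose))
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the whole pipeline on the synthetic scenario
#'
#' Executes simulate -> te-catalog -> ecc-peaks -> ecc-structure (decompose,
#' classify, divergence, origin) -> wgs (snps, density, introgressions, teis)
#' and writes every stage table plus a JSON/markdown report including
#' recovery metrics against the simulation truth.
#'
#' @param cfg a [run_config()].
#' @return list of class `mobilome_run` with all stage results and the report.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- aligner_params()

  log_msg(cfg, "simulate", "reference + reads (seed ", cfg$seed, ")")
  sim <- simulate_reference(cfg$sim)
  ecc <- list(treatment = simulate_eccdna_reads(sim, "treatment"),
              control = simulate_eccdna_reads(sim, "control"))
  wgs <- simulate_wgs_reads(sim)
  write_simulation(sim, cfg$out_dir, ecc = ecc, wgs = wgs)

  log_msg(cfg, "te-catalog", nrow(sim$annotation), " elements")
  cat_res <- te_catalog(sim$genome, sim$annotation,
                        linkage_threshold = cfg$linkage_threshold)
  utils::write.table(cat_res$catalog, file.path(cfg$out_dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_msg(cfg, "ecc-peaks", "mapping ", length(ecc$treatment$reads), "+",
          length(ecc$control$reads), " reads")
  idx <- build_reference_index(sim$genome, k = params$k)
  # counting uses primary records only; capping the reported secondaries
  # skips full alignment of repeat-family multi-mapping candidates
  count_params <- aligner_params(max_hits = 1L, max_split_hits = 0L)
  aln_t <- map_reads(ecc$treatment$reads, idx, count_params, primary_only = TRUE)
  aln_c <- map_reads(ecc$control$reads, idx, count_params, primary_only = TRUE)
  write_paf(aln_t, file.path(cfg$out_dir, "ecc_treatment.paf"))
  write_paf(aln_c, file.path(cfg$out_dir, "ecc_control.paf"))
  cnt_t <- count_reads_per_element(aln_t, sim$annotation, cfg$min_overlap)
  cnt_c <- count_reads_per_element(aln_c, sim$annotation, cfg$min_overlap)
  peaks <- call_differential(cnt_t$counts, cnt_c$counts,
                             totals = c(length(ecc$treatment$reads),
                                        length(ecc$control$reads)),
                             min_reads = cfg$min_reads, alpha = cfg$alpha,
                             method = cfg$correction)
  utils::write.table(peaks, file.path(cfg$out_dir, "peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig <- peaks$element_id[peaks$status == "significant"]

  log_msg(cfg, "ecc-structure", length(sig), " significant element(s)")
  set.seed(cfg$seed + 23L)
  top <- utils::head(sig[order(-peaks$cpm100k_treat[match(sig, peaks$element_id)])],
                     cfg$structure_top)
  structures <- list()
  divergence <- list()
  origins <- list()
  panel <- simulate_relative_panel(sim, cfg$panel_divergence)
  for (id in top) {
    ann_row <- sim$annotation[sim$annotation$id == id, ]
    eseq <- element_sequence(sim, id)
    rid <- aln_t$query_id[aln_t$target_id == ann_row$chrom &
                            pmin(aln_t$target_end, ann_row$end) -
                            pmax(aln_t$target_start, ann_row$start) >=
                            cfg$min_overlap]
    rid <- utils::head(rid, cfg$structure_reads)
    decomps <- lapply(rid, function(r)
      decompose_concatemer(ecc$treatment$reads[[r]], eseq, read_id = r,
                           element_id = id))
    decomps <- Filter(function(d) nrow(d$hits) > 0, decomps)
    calls <- lapply(decomps, classify_structure, element = ann_row)
    structures[[id]] <- data.frame(
      element_id = id,
      read_id = vapply(calls, `[[`, character(1), "read_id"),
      class = vapply(calls, `[[`, character(1), "class"),
      internal_coverage = vapply(calls, `[[`, numeric(1), "internal_coverage"),
      n_ltr_copies = vapply(calls, `[[`, integer(1), "n_ltr_copies"),
      monomer_len = vapply(decomps, `[[`, numeric(1), "monomer_len"),
      n_full_monomers = vapply(decomps, `[[`, integer(1), "n_full_monomers"),
      stringsAsFactors = FALSE)
    div <- consensus_divergence(decomps, eseq, ann_row)
    divergence[[id]] <- data.frame(element_id = id, snp_count = div$snp_count,
                                   ltr_covered = div$ltr_covered,
                                   ltr_deletion = !is.null(div$ltr_deletion),
                                   mean_depth = div$mean_depth,
                                   stringsAsFactors = FALSE)
    # consensus LTR for origin assignment: LTR part of the eccDNA consensus
    cons <- Filter(nzchar, vapply(decomps, `[[`, character(1), "consensus"))
    if (length(cons)) {
      # rebuild a pooled consensus restricted to the 5' LTR
      pooled <- consensus_pooled(decomps, nchar(eseq))
      l5 <- substr(pooled, ann_row$ltr5_start + 1L, ann_row$ltr5_end)
      l3 <- substr(pooled, ann_row$ltr3_start + 1L, ann_row$ltr3_end)
      qltr <- if (sum(strsplit(l5, "")[[1]] != "N") >=
                  sum(strsplit(l3, "")[[1]] != "N")) l5 else l3
      qltr <- gsub("N", "", qltr)
      if (nchar(qltr) >= 100) {
        oc <- assign_origin(qltr, panel, cfg$identity_floor, cfg$min_margin,
                            params)
        origins[[id]] <- data.frame(element_id = id, assigned = oc$assigned,
                                    margin = oc$margin,
                                    best_identity = max(oc$per_genome$best_identity),
                                    stringsAsFactors = FALSE)
      }
    }
  }
  bind_or_empty <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  structures <- bind_or_empty(structures,
                              data.frame(element_id = character(),
                                         read_id = character(),
                                         class = character()))
  divergence <- bind_or_empty(divergence, data.frame(element_id = character()))
  origins <- bind_or_empty(origins, data.frame(element_id = character(),
                                               assigned = character()))
  utils::write.table(structures, file.path(cfg$out_dir, "structures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(divergence, file.path(cfg$out_dir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(origins, file.path(cfg$out_dir, "origin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_msg(cfg, "wgs", "mapping ", length(wgs$reads), " reads")
  aln_w <- map_reads(wgs$reads, idx, aligner_params(max_hits = 4L))
  snps <- call_snps_naive(aln_w, wgs$reads, sim$genome)
  write_vcf_min(snps, file.path(cfg$out_dir, "snps.vcf"))
  chrom_lengths <- stats::setNames(nchar(sim$genome), names(sim$genome))
  track <- snp_density_windows(snps, chrom_lengths, cfg$window_size)
  utils::write.table(track$windows, file.path(cfg$out_dir, "density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  segs <- segment_introgressions(track, cfg$fold_threshold, cfg$min_windows,
                                 cfg$max_gap)
  utils::write.table(segs, file.path(cfg$out_dir, "introgressions.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  lib <- stats::setNames(
    vapply(sim$truth$families, `[[`, character(1), "consensus"),
    names(sim$truth$families))
  teis <- call_teis(aln_w, wgs$reads, lib, sim$genome, cfg$min_insert,
                    cfg$min_support, cfg$cluster_radius, params)
  utils::write.table(teis, file.path(cfg$out_dir, "teis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # recovery metrics against truth
  truth_active <- sim$truth$active_elements
  sig_set <- sig
  intro <- cfg$sim$introgression
  tei_truth <- sim$truth$insertions
  tei_match <- vapply(seq_len(nrow(tei_truth)), function(i)
    any(teis$chrom == tei_truth$chrom[i] &
          abs(teis$position - tei_truth$pos[i]) <= 50), logical(1))
  report <- list(
    seed = cfg$seed,
    n_elements = nrow(sim$annotation),
    n_tested = sum(peaks$status != "low_count"),
    n_significant = length(sig_set),
    significant_elements = sig_set,
    activity_recall = mean(truth_active %in% sig_set),
    activity_precision = if (length(sig_set))
      mean(sig_set %in% truth_active) else NA,
    structure_classes = if (nrow(structures))
      as.list(table(structures$class)) else list(),
    origin_assignments = if (nrow(origins))
      stats::setNames(as.list(origins$assigned), origins$element_id) else list(),
    n_snps = nrow(snps),
    introgression_segments = segs,
    introgression_recovered = any(segs$chrom == intro$chrom &
                                    abs(segs$start - intro$start) <= cfg$window_size &
                                    abs(segs$end - intro$end) <= cfg$window_size),
    n_teis = nrow(teis),
    tei_recall = mean(tei_match),
    tei_precision = if (nrow(teis)) mean(vapply(seq_len(nrow(teis)), function(i)
      any(tei_truth$chrom == teis$chrom[i] &
            abs(tei_truth$pos - teis$position[i]) <= 50), logical(1))) else NA)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  md <- c("# Mobilome pipeline report", "",
          sprintf("- seed: %d", cfg$seed),
          sprintf("- elements annotated: %d", report$n_elements),
          sprintf("- elements tested: %d", report$n_tested),
          sprintf("- significant elements: %d (%s)", report$n_significant,
                  paste(report$significant_elements, collapse = ", ")),
          sprintf("- activity recall/precision vs truth: %.2f / %.2f",
                  report$activity_recall, report$activity_precision),
          sprintf("- SNPs called: %d", report$n_snps),
          sprintf("- introgression segments: %d (planted segment recovered: %s)",
                  nrow(segs), report$introgression_recovered),
          sprintf("- TEIs called: %d (recall %.2f, precision %.2f)",
                  report$n_teis, report$tei_recall, report$tei_precision))
  writeLines(md, file.path(cfg$out_dir, "report.md"))
  # echo effective configuration next to the outputs
  cfg_out <- cfg
  cfg_out$sim <- unclass(cfg_out$sim)
  jsonlite::write_json(unclass(cfg_out), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(sim = sim, catalog = cat_res$catalog, peaks = peaks,
                 structures = structures, divergence = divergence,
                 origins = origins, snps = snps, density = track,
                 introgressions = segs, teis = teis, report = report,
                 config = cfg),
            class = "mobilome_run")
}

# pooled per-column consensus over decompositions ('N' where uncalled)
consensus_pooled <- function(decomps, elen) {
  pile <- matrix(0L, 7, elen)
  for (d in decomps) if (!is.null(d$pile_full)) pile <- pile + d$pile_full
  bases <- c("A", "C", "G", "T")
  top <- apply(pile[1:4, , drop = FALSE], 2, which.max)
  cnt <- pile[cbind(top, seq_len(elen))]
  depth <- colSums(pile[c(1:4, 6), , drop = FALSE])
  ok <- depth >= 2 & cnt / pmax(depth, 1) >= 0.5 & cnt > pile[6, ]
  out <- ifelse(ok, bases[top], "N")
  paste(out, collapse = "")
}

#' @export
print.mobilome_run <- function(x, ...) {
  cat("mobilome pipeline run\n")
  cat(sprintf("  significant elements: %d (recall %.2f, precision %.2f)\n",
              x$report$n_significant, x$report$activity_recall,
              x$report$activity_precision))
  cat(sprintf("  SNPs: %d; introgression segments: %d; TEIs: %d\n",
              x$report$n_snps, nrow(x$introgressions), x$report$n_teis))
  invisible(x)
}
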