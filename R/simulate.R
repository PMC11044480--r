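#' Configuration of the synthetic mobilome scenario
#'
#' Defines the desk-scale study conditions emulated by the generators: a small
#' multi-chromosome genome with planted LTR retrotransposon families (two of
#' which carry a transpositionally active master copy), rolling-circle
#' concatemer eccDNA reads for a treated and a control condition, and
#' whole-genome long reads from a donor haplotype with an elevated-SNP
#' introgressed segment and non-reference TE insertions.
#'
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param chrom_lengths named integer vector of host chromosome lengths (bp,
#'   before element insertion).
#' @param gc GC fraction of host sequence.
#' @param n_families number of planted LTR-RTE families.
#' @param copies_per_family copies planted per family.
#' @param ltr_len_range,internal_len_range uniform ranges (bp) for family LTR
#'   and internal-region lengths.
#' @param planted_orf_lengths list of codon counts planted per family
#'   (recycled across families). Defaults are the reading-frame lengths of the
#'   two active families (1302; 352 + 1173 codons).
#' @param copy_divergence range of per-copy substitution divergence from the
#'   family consensus (master copies of active families stay identical).
#' @param active_families indices of families whose master copy is
#'   transpositionally active (produces eccDNA; enriched under treatment).
#' @param enrichment_fold eccDNA read enrichment of active elements in the
#'   treatment relative to control.
#' @param donor_snps substitutions planted on the eccDNA donor allele of each
#'   active element (the circles derive from a diverged non-reference copy).
#' @param ecc_mix named fractions over circle structural classes
#'   (solo_LTR, full_1LTR, full_2LTR, truncated); must sum to 1. Either one
#'   vector for both conditions or `list(treatment=, control=)`.
#' @param reads_per_condition eccDNA reads per condition.
#' @param read_len_meanlog,read_len_sdlog lognormal eccDNA read-length model.
#' @param error_rates per-base substitution, insertion and deletion rates.
#' @param background_snp_rate donor-vs-reference SNP rate per bp.
#' @param introgression list(chrom, start, end, fold): segment whose SNP rate
#'   is `fold` times the background.
#' @param insertions either NULL (plant `n_insertions` automatically) or a
#'   data.frame with family, chrom, pos, tsd_len.
#' @param n_insertions number of auto-planted non-reference TE insertions;
#'   the default mirrors a scenario with three insertions of family 1 and one
#'   of family 2.
#' @param tsd_len target-site duplication length (4-6 bp).
#' @param wgs_depth fold coverage of the whole-genome read set.
#' @param wgs_len_meanlog,wgs_len_sdlog lognormal WGS read-length model.
#' @param min_gap minimum spacing (bp) between planted elements.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 400000L, chr2 = 300000L),
                       gc = 0.36,
                       n_families = 5L,
                       copies_per_family = 8L,
                       ltr_len_range = c(400L, 600L),
                       internal_len_range = c(3800L, 4600L),
                       planted_orf_lengths = list(1302L, c(352L, 1173L)),
                       copy_divergence = c(0.01, 0.05),
                       active_families = c(1L, 2L),
                       enrichment_fold = 10,
                       donor_snps = 55L,
                       ecc_mix = c(solo_LTR = 0.15, full_1LTR = 0.55,
                                   full_2LTR = 0.15, truncated = 0.15),
                       reads_per_condition = 5000L,
                       read_len_meanlog = log(3000),
                       read_len_sdlog = 0.35,
                       error_rates = c(sub = 0.05, ins = 0.025, del = 0.025),
                       background_snp_rate = 5e-4,
                       introgression = list(chrom = "chr1", start = 100000L,
                                            end = 300000L, fold = 20),
                       insertions = NULL,
                       n_insertions = 4L,
                       tsd_len = 5L,
                       wgs_depth = 20,
                       wgs_len_meanlog = log(8000),
                       wgs_len_sdlog = 0.3,
                       min_gap = 1500L) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$chrom_lengths)))
    names(cfg$chrom_lengths) <- paste0("chr", seq_along(cfg$chrom_lengths))
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (cfg$gc < 0 || cfg$gc > 1) stop("gc must be in [0,1]")
  mixes <- if (is.list(cfg$ecc_mix)) cfg$ecc_mix else list(cfg$ecc_mix)
  for (m in mixes) {
    if (abs(sum(m) - 1) > 1e-8) stop("ecc_mix must sum to 1")
    if (any(m < 0)) stop("ecc_mix fractions must be in [0,1]")
    if (!all(names(m) %in% c("solo_LTR", "full_1LTR", "full_2LTR", "truncated")))
      stop("unknown eccDNA structure class in ecc_mix")
  }
  if (any(cfg$error_rates < 0) || sum(cfg$error_rates) >= 1)
    stop("error rates must be non-negative and sum to < 1")
  if (cfg$tsd_len < 4 || cfg$tsd_len > 6) stop("tsd_len must be 4-6 bp")
  if (any(cfg$active_families > cfg$n_families))
    stop("active_families out of range")
  structure(cfg, class = "sim_config")
}

#' Random DNA sequence
#' @param n length in bp.
#' @param gc GC fraction.
#' @return character scalar.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# an open reading frame of `codons` codons (ATG..last sense codon) followed by
# a TAA stop; reported ORF length excludes the stop
make_orf <- function(codons) {
  sense <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(sense, STOP_CODONS)
  body <- sample(sense, codons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# substitute `n` random positions (or positions given) with different bases
mutate_subst <- function(seq, n = NULL, rate = NULL, positions = NULL) {
  L <- nchar(seq)
  if (is.null(positions)) {
    if (is.null(n)) n <- stats::rbinom(1, L, rate)
    n <- min(n, L)
    positions <- sample.int(L, n)
  }
  if (!length(positions)) return(list(seq = seq, positions = integer()))
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1)
  }
  list(seq = paste(ch, collapse = ""), positions = sort(positions))
}

build_family <- function(cfg, fam_idx) {
  ltr_len <- sample(cfg$ltr_len_range[1]:cfg$ltr_len_range[2], 1)
  orf_plan <- cfg$planted_orf_lengths[[
    ((fam_idx - 1L) %% length(cfg$planted_orf_lengths)) + 1L]]
  spacer <- 20L
  need <- sum(3L * orf_plan + 3L) + (length(orf_plan) + 1L) * (spacer + 3L)
  internal_len <- max(sample(cfg$internal_len_range[1]:cfg$internal_len_range[2], 1),
                      need)
  pieces <- character(0)
  orf_offsets <- integer(0)   # 0-based offsets within internal region
  cur <- 0L
  for (cod in orf_plan) {
    pre <- paste0(random_dna(spacer, cfg$gc), "TAA")  # in-frame stop guard
    pieces <- c(pieces, pre)
    cur <- cur + nchar(pre)
    orf <- make_orf(cod)
    orf_offsets <- c(orf_offsets, cur)
    pieces <- c(pieces, orf)
    cur <- cur + nchar(orf)
  }
  tail_len <- internal_len - cur
  pieces <- c(pieces, random_dna(tail_len, cfg$gc))
  internal <- paste(pieces, collapse = "")
  ltr <- random_dna(ltr_len, cfg$gc)
  list(family = paste0("FAM", fam_idx), ltr = ltr, internal = internal,
       ltr_len = ltr_len, internal_len = nchar(internal),
       consensus = paste0(ltr, internal, ltr),
       orf_codons = orf_plan, orf_offsets = orf_offsets)
}

#' Simulate the reference genome with planted LTR retrotransposons
#'
#' Each planted element is LTR + internal region + LTR inserted with a
#' target-site duplication. Families are generated independently (mutually
#' far below 80% identity); copies within a family diverge from the consensus
#' by substitutions only, so within-family identity stays >= 90%. The master
#' copy of each active family is planted unmutated (LTR identity 100), and a
#' diverged eccDNA donor allele is recorded for it.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `mobilome_sim` with `genome` (named character),
#'   `annotation` (TE data.frame), and `truth` (ground-truth list: family
#'   consensus sequences, element sequences, active element ids, donor
#'   templates and divergent sites, planted insertion sites).
#' @export
simulate_reference <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  families <- lapply(seq_len(cfg$n_families), function(i) build_family(cfg, i))
  names(families) <- vapply(families, `[[`, character(1), "family")

  # plan copies
  copies <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- families[[f]]
    for (c in seq_len(cfg$copies_per_family)) {
      master <- (f %in% cfg$active_families) && c == 1L
      if (master) {
        seq <- fam$consensus
        div <- integer(0)
      } else {
        d <- stats::runif(1, cfg$copy_divergence[1], cfg$copy_divergence[2])
        mut <- mutate_subst(fam$consensus, n = round(d * nchar(fam$consensus)))
        seq <- mut$seq
        div <- mut$positions
      }
      copies[[length(copies) + 1L]] <-
        list(family = fam$family, fam_idx = f, master = master, seq = seq,
             ltr_len = fam$ltr_len, internal_len = fam$internal_len,
             strand = sample(c("+", "-"), 1))
    }
  }

  # place copies on chromosomes with minimum spacing, leaving room at the ends
  chroms <- names(cfg$chrom_lengths)
  placement <- data.frame(chrom = character(), pos = integer(), idx = integer(),
                          stringsAsFactors = FALSE)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  total_need <- sum(vapply(copies, function(x) nchar(x$seq), numeric(1))) +
    length(copies) * cfg$min_gap
  if (total_need > sum(cfg$chrom_lengths) * 0.9)
    stop("planted elements exceed chromosome capacity")
  for (i in seq_along(copies)) {
    placed <- FALSE
    for (try in 1:500) {
      ch <- sample(chroms, 1, prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
      L <- cfg$chrom_lengths[[ch]]
      p <- sample.int(L - 2000L, 1) + 1000L
      ok <- TRUE
      for (iv in occupied[[ch]])
        if (p > iv[1] - cfg$min_gap && p < iv[2] + cfg$min_gap) { ok <- FALSE; break }
      if (ok) {
        occupied[[ch]] <- c(occupied[[ch]], list(c(p, p)))
        placement <- rbind(placement, data.frame(chrom = ch, pos = p, idx = i,
                                                 stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("planted elements exceed chromosome capacity")
  }

  # build chromosomes; insert left-to-right, tracking coordinate offsets
  genome <- character(length(chroms))
  names(genome) <- chroms
  ann <- list()
  tsd <- cfg$tsd_len
  for (ch in chroms) {
    host <- random_dna(cfg$chrom_lengths[[ch]], cfg$gc)
    rows <- placement[placement$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    parts <- character(0)
    prev <- 0L   # host position consumed (0-based)
    offset <- 0L
    for (r in seq_len(nrow(rows))) {
      cp <- copies[[rows$idx[r]]]
      p <- rows$pos[r]
      site <- substr(host, p + 1L, p + tsd)
      parts <- c(parts, substr(host, prev + 1L, p + tsd))
      gseq <- if (cp$strand == "+") cp$seq else revcomp(cp$seq)
      start <- p + tsd + offset
      parts <- c(parts, gseq)
      offset <- offset + nchar(gseq) + tsd
      prev <- p   # duplicate the target site after the element
      elen <- nchar(cp$seq)
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + elen, strand = cp$strand,
        family = cp$family, ltr5_start = 0L, ltr5_end = cp$ltr_len,
        ltr3_start = elen - cp$ltr_len, ltr3_end = elen,
        tsd = site, master = cp$master, idx = rows$idx[r],
        stringsAsFactors = FALSE)
    }
    parts <- c(parts, substr(host, prev + 1L, nchar(host)))
    genome[[ch]] <- paste(parts, collapse = "")
  }
  ann <- do.call(rbind, ann)
  ann <- ann[order(match(ann$chrom, chroms), ann$start), , drop = FALSE]
  ann$id <- sprintf("RTE%03d", seq_len(nrow(ann)))
  ann <- ann[, c("id", "chrom", "start", "end", "strand", "family",
                 "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                 "tsd", "master", "idx")]
  rownames(ann) <- NULL

  element_seqs <- stats::setNames(
    vapply(seq_len(nrow(ann)), function(i) copies[[ann$idx[i]]]$seq, character(1)),
    ann$id)
  active <- ann$id[ann$master]

  # eccDNA donor allele per active element: diverged by donor_snps substitutions
  donor_templates <- list()
  divergent_sites <- list()
  for (id in active) {
    mut <- mutate_subst(element_seqs[[id]], n = cfg$donor_snps)
    donor_templates[[id]] <- mut$seq
    divergent_sites[[id]] <- mut$positions - 1L   # 0-based element offsets
  }

  # planted non-reference insertion sites (never inside an annotated element)
  ins <- cfg$insertions
  if (is.null(ins)) {
    fams <- rep(c("FAM1", "FAM2"), times = c(max(cfg$n_insertions - 1L, 0L), 1L))
    fams <- fams[seq_len(cfg$n_insertions)]
    ins <- data.frame(family = fams, chrom = NA_character_, pos = NA_integer_,
                      tsd_len = cfg$tsd_len, stringsAsFactors = FALSE)
    ins$strand <- sample(c("+", "-"), nrow(ins), replace = TRUE)
    ins$seq <- vapply(seq_len(nrow(ins)), function(i) {
      s <- families[[ins$family[i]]]$consensus
      if (ins$strand[i] == "+") s else revcomp(s)
    }, character(1))
    for (i in seq_len(nrow(ins))) {
      first <- substr(ins$seq[i], 1L, 1L)
      last <- substr(ins$seq[i], nchar(ins$seq[i]), nchar(ins$seq[i]))
      for (try in 1:2000) {
        ch <- sample(chroms, 1)
        g <- genome[[ch]]
        p <- sample.int(nchar(g) - 4000L, 1) + 2000L
        hit <- ann$chrom == ch & p > ann$start - 2000L & p < ann$end + 2000L
        near <- !is.na(ins$pos) & ins$chrom == ch & abs(ins$pos - p) < 5000L
        # keep the planted target-site duplication unambiguous: no
        # micro-homology between the insert ends and the flanking bases
        clean <- substr(g, p + tsd + 1L, p + tsd + 1L) != first &&
          substr(g, p, p) != last
        if (!any(hit) && !any(near) && clean) {
          ins$chrom[i] <- ch; ins$pos[i] <- p
          break
        }
      }
    }
    if (any(is.na(ins$pos))) stop("could not place non-reference insertions")
  } else {
    for (i in seq_len(nrow(ins))) {
      hit <- ann$chrom == ins$chrom[i] & ins$pos[i] > ann$start &
        ins$pos[i] < ann$end
      if (any(hit))
        stop("insertion position inside an annotated element")
    }
    if (is.null(ins$strand))
      ins$strand <- sample(c("+", "-"), nrow(ins), replace = TRUE)
    if (is.null(ins$seq))
      ins$seq <- vapply(seq_len(nrow(ins)), function(i) {
        s <- families[[ins$family[i]]]$consensus
        if (ins$strand[i] == "+") s else revcomp(s)
      }, character(1))
  }

  truth <- list(config = cfg, families = families, element_seqs = element_seqs,
                active_elements = active, donor_templates = donor_templates,
                divergent_sites = divergent_sites, insertions = ins,
                orf_catalog = lapply(families, function(f)
                  list(codons = f$orf_codons, offsets = f$orf_offsets,
                       ltr_len = f$ltr_len)))
  structure(list(genome = genome,
                 annotation = ann[, setdiff(names(ann), c("idx"))],
                 truth = truth),
            class = "mobilome_sim")
}

#' @export
print.mobilome_sim <- function(x, ...) {
  cat(sprintf("synthetic mobilome: %d chromosome(s), %s bp; %d planted elements (%d active)\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$annotation), length(x$truth$active_elements)))
  invisible(x)
}

#' Extract an element sequence in element orientation from the genome
#' @param sim a `mobilome_sim` (or list with genome + annotation).
#' @param id element id.
#' @return character scalar.
#' @export
element_sequence <- function(sim, id) {
  a <- sim$annotation[sim$annotation$id == id, ]
  if (!nrow(a)) stop("unknown element id")
  s <- substr(sim$genome[[a$chrom]], a$start + 1L, a$end)
  if (a$strand == "-") s <- revcomp(s)
  s
}

#' Build one eccDNA circle sequence for an element
#'
#' Structural classes: `solo_LTR` (one LTR only), `full_1LTR` (internal region
#' plus one LTR, the circularisation product of the full element after
#' LTR-LTR recombination), `full_2LTR` (entire element), `truncated`
#' (a contiguous internal subsequence covering 10-90% of the internal region).
#'
#' @param element_seq element sequence (element orientation).
#' @param ltr_len LTR length of the element's family.
#' @param class structure class.
#' @param truncated_frac internal fraction for class "truncated" (NULL: drawn
#'   uniformly from \[0.1, 0.9\]).
#' @param internal_deletion optional c(offset, len), 0-based within the
#'   internal region, removed from the circle (emulates small deletions).
#' @param drop_ltr if TRUE, the LTR part is left out (internal-only circle).
#' @param ltr_deletion optional c(offset, len) removed from the circle's LTR.
#' @return circle sequence (character). Errors if shorter than 50 bp.
#' @export
build_circle <- function(element_seq, ltr_len, class = "full_1LTR",
                         truncated_frac = NULL, internal_deletion = NULL,
                         drop_ltr = FALSE, ltr_deletion = NULL) {
  L <- nchar(element_seq)
  ltr5 <- substr(element_seq, 1L, ltr_len)
  ltr3 <- substr(element_seq, L - ltr_len + 1L, L)
  internal <- substr(element_seq, ltr_len + 1L, L - ltr_len)
  if (!is.null(internal_deletion)) {
    s <- internal_deletion[1]; l <- internal_deletion[2]
    internal <- paste0(substr(internal, 1L, s),
                       substr(internal, s + l + 1L, nchar(internal)))
  }
  if (!is.null(ltr_deletion)) {
    s <- ltr_deletion[1]; l <- ltr_deletion[2]
    ltr3 <- paste0(substr(ltr3, 1L, s), substr(ltr3, s + l + 1L, nchar(ltr3)))
    ltr5 <- paste0(substr(ltr5, 1L, s), substr(ltr5, s + l + 1L, nchar(ltr5)))
  }
  circ <- switch(class,
    solo_LTR = ltr5,
    full_1LTR = if (drop_ltr) internal else paste0(internal, ltr3),
    full_2LTR = if (drop_ltr) internal else paste0(ltr5, internal, ltr3),
    truncated = {
      if (is.null(truncated_frac)) truncated_frac <- stats::runif(1, 0.1, 0.9)
      len <- max(1L, round(truncated_frac * nchar(internal)))
      start <- sample.int(nchar(internal) - len + 1L, 1)
      substr(internal, start, start + len - 1L)
    },
    stop("unknown structure class"))
  if (nchar(circ) < 50L) stop("circle shorter than 50 bp")
  circ
}

# one rolling-circle concatemer read: tandem copies from a uniform phase
rca_read <- function(circle, read_len) {
  clen <- nchar(circle)
  phase <- sample.int(clen, 1) - 1L
  reps <- ceiling((phase + read_len) / clen)
  lin <- paste(rep(circle, reps), collapse = "")
  substr(lin, phase + 1L, phase + read_len)
}

#' Simulate eccDNA nanopore-like concatemer reads for one condition
#'
#' Every read originates from one element's circle: the element is drawn with
#' weights 1 for inactive and `enrichment_fold` (treatment only) for active
#' elements; the structure class is drawn from `ecc_mix`; the read is a tandem
#' concatemer of the circle starting at a uniform phase, with length from the
#' lognormal model, in random orientation, corrupted by the per-base error
#' model. Circles of active elements derive from the recorded donor allele.
#'
#' @param sim a `mobilome_sim` from [simulate_reference()].
#' @param condition "treatment" or "control".
#' @param n_reads number of reads (default from the config).
#' @param seed seed (default derived from the config seed and condition).
#' @param error_rates per-base error rates (default from the config; a run
#'   with c(0,0,0) and the same seed yields the error-free templates of the
#'   same reads).
#' @return list with `reads` (named character vector) and `read_truth`
#'   (data.frame: read_id, element_id, class, circle_len, phase-free).
#' @export
simulate_eccdna_reads <- function(sim, condition = c("treatment", "control"),
                                  n_reads = NULL, seed = NULL,
                                  error_rates = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$truth$config
  if (is.null(n_reads)) n_reads <- cfg$reads_per_condition
  if (is.null(error_rates)) error_rates <- cfg$error_rates
  if (is.null(seed))
    seed <- cfg$seed + ifelse(condition == "treatment", 11L, 13L)
  set.seed(seed)
  ann <- sim$annotation
  mix <- if (is.list(cfg$ecc_mix)) cfg$ecc_mix[[condition]] else cfg$ecc_mix
  w <- rep(1, nrow(ann))
  if (condition == "treatment")
    w[ann$id %in% sim$truth$active_elements] <- cfg$enrichment_fold
  fam_ltr <- vapply(sim$truth$families, `[[`, numeric(1), "ltr_len")

  el <- sample(ann$id, n_reads, replace = TRUE, prob = w)
  cls <- sample(names(mix), n_reads, replace = TRUE, prob = mix)
  lens <- pmin(pmax(round(stats::rlnorm(n_reads, cfg$read_len_meanlog,
                                        cfg$read_len_sdlog)), 300L), 50000L)
  reads <- character(n_reads)
  circle_len <- integer(n_reads)
  flip <- stats::runif(n_reads) < 0.5
  for (i in seq_len(n_reads)) {
    id <- el[i]
    eseq <- if (id %in% sim$truth$active_elements)
      sim$truth$donor_templates[[id]] else sim$truth$element_seqs[[id]]
    fam <- ann$family[ann$id == id]
    circ <- build_circle(eseq, fam_ltr[[fam]], cls[i])
    circle_len[i] <- nchar(circ)
    r <- rca_read(circ, lens[i])
    reads[i] <- if (flip[i]) revcomp(r) else r
  }
  if (sum(error_rates) > 0)
    reads <- as.character(mb_corrupt(reads, error_rates[["sub"]],
                                     error_rates[["ins"]],
                                     error_rates[["del"]]))
  ids <- sprintf("%s_read%06d", condition, seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       read_truth = data.frame(read_id = ids, element_id = el, class = cls,
                               circle_len = circle_len, flipped = flip,
                               stringsAsFactors = FALSE))
}

# sample SNP positions over [0, L) at a per-bp rate, plus an optional elevated
# segment; returns 0-based unique sorted positions
sample_snp_positions <- function(L, rate, seg = NULL) {
  n <- stats::rbinom(1, L, rate)
  pos <- if (n > 0) sample.int(L, n) - 1L else integer()
  if (!is.null(seg)) {
    slen <- seg$end - seg$start
    n2 <- stats::rbinom(1, slen, rate * (seg$fold - 1))
    if (n2 > 0) pos <- c(pos, seg$start + sample.int(slen, n2) - 1L)
  }
  sort(unique(pos))
}

#' Simulate whole-genome long reads from a donor haplotype
#'
#' The donor differs from the reference by background SNPs, an introgressed
#' segment with `fold`-times the background SNP rate, and the planted
#' non-reference TE insertions (full family consensus copy flanked by a
#' duplicated target site). Reads are drawn uniformly at the configured
#' coverage and corrupted by the error model.
#'
#' @param sim a `mobilome_sim`.
#' @param depth fold coverage (default from config).
#' @param error_rates per-base error rates (default from config; set to
#'   c(0,0,0) for error-free reads).
#' @param seed seed (default derived from config seed).
#' @return list with `reads`, `variants` (truth SNPs, reference 0-based
#'   coordinates), `insertions` (truth TEI table), `introgression`.
#' @export
simulate_wgs_reads <- function(sim, depth = NULL, error_rates = NULL,
                               seed = NULL) {
  cfg <- sim$truth$config
  if (is.null(depth)) depth <- cfg$wgs_depth
  if (is.null(error_rates)) error_rates <- cfg$error_rates
  if (is.null(seed)) seed <- cfg$seed + 17L
  set.seed(seed)
  intro <- cfg$introgression
  variants <- list()
  donor <- character(length(sim$genome))
  names(donor) <- names(sim$genome)
  ins_truth <- sim$truth$insertions
  for (ch in names(sim$genome)) {
    ref <- sim$genome[[ch]]
    L <- nchar(ref)
    seg <- if (!is.null(intro) && intro$chrom == ch)
      list(start = intro$start, end = min(intro$end, L), fold = intro$fold) else NULL
    pos <- sample_snp_positions(L, cfg$background_snp_rate, seg)
    refb <- if (length(pos)) substring(ref, pos + 1L, pos + 1L) else character()
    keep <- refb %in% c("A", "C", "G", "T")
    pos <- pos[keep]; refb <- refb[keep]
    altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
    dch <- ref
    if (length(pos)) {
      chv <- strsplit(dch, "")[[1]]
      chv[pos + 1L] <- altb
      dch <- paste(chv, collapse = "")
    }
    # splice in the planted insertions (descending position)
    rows <- which(ins_truth$chrom == ch)
    rows <- rows[order(-ins_truth$pos[rows])]
    for (i in rows) {
      p <- ins_truth$pos[i]
      # ins_truth$seq is already strand-adjusted (genome orientation)
      dch <- paste0(substr(dch, 1L, p + ins_truth$tsd_len[i]), ins_truth$seq[i],
                    substr(dch, p + 1L, nchar(dch)))
    }
    donor[[ch]] <- dch
    if (length(pos))
      variants[[ch]] <- data.frame(chrom = ch, pos = pos, ref = refb,
                                   alt = unname(altb),
                                   in_introgression = !is.null(seg) &
                                     pos >= (if (is.null(seg)) 0 else seg$start) &
                                     pos < (if (is.null(seg)) 0 else seg$end),
                                   stringsAsFactors = FALSE)
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), in_introgression = logical())
  rownames(variants) <- NULL

  mean_len <- exp(cfg$wgs_len_meanlog + cfg$wgs_len_sdlog^2 / 2)
  reads <- list()
  for (ch in names(donor)) {
    L <- nchar(donor[[ch]])
    n <- max(1L, round(depth * L / mean_len))
    lens <- pmin(pmax(round(stats::rlnorm(n, cfg$wgs_len_meanlog,
                                          cfg$wgs_len_sdlog)), 1000L), 60000L)
    starts <- sample.int(L, n, replace = TRUE) - 1L
    rs <- substring(donor[[ch]], starts + 1L, pmin(starts + lens, L))
    keep <- nchar(rs) >= 1000L
    rs <- rs[keep]
    flip <- stats::runif(length(rs)) < 0.5
    rs[flip] <- revcomp(rs[flip])
    reads[[ch]] <- rs
  }
  reads <- unlist(reads, use.names = FALSE)
  if (sum(error_rates) > 0)
    reads <- as.character(mb_corrupt(reads, error_rates[["sub"]],
                                     error_rates[["ins"]], error_rates[["del"]]))
  names(reads) <- sprintf("wgs_read%06d", seq_along(reads))
  list(reads = reads, variants = variants,
       insertions = ins_truth[, c("family", "chrom", "pos", "tsd_len", "strand")],
       introgression = intro)
}

#' Simulate a variant-level SNP landscape (no reads)
#'
#' Draws SNP positions directly at a background per-bp rate with one elevated
#' introgressed segment, for exercising density windowing and segmentation at
#' chromosome scale without sequence-level simulation.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param rate background SNP rate per bp.
#' @param introgression list(chrom, start, end, fold) or NULL.
#' @param seed integer seed.
#' @return data.frame with chrom, pos (0-based).
#' @export
simulate_snp_landscape <- function(chrom_lengths, rate = 1e-4,
                                   introgression = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  out <- list()
  for (ch in names(chrom_lengths)) {
    seg <- if (!is.null(introgression) && introgression$chrom == ch)
      introgression else NULL
    pos <- sample_snp_positions(chrom_lengths[[ch]], rate, seg)
    if (length(pos))
      out[[ch]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a simulation to disk (FASTA/BED/FASTQ/JSON)
#'
#' @param sim a `mobilome_sim`.
#' @param dir output directory (created if needed).
#' @param ecc optional list(treatment=, control=) from
#'   [simulate_eccdna_reads()].
#' @param wgs optional result of [simulate_wgs_reads()].
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir, ecc = NULL, wgs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_te_bed(sim$annotation, file.path(dir, "te_annotation.bed"))
  truth <- list(active_elements = sim$truth$active_elements,
                annotation = sim$annotation,
                divergent_sites = sim$truth$divergent_sites,
                insertions = sim$truth$insertions[, c("family", "chrom", "pos",
                                                      "tsd_len", "strand")],
                introgression = sim$truth$config$introgression)
  if (!is.null(ecc)) {
    write_fastq(ecc$treatment$reads, file.path(dir, "ecc_treatment.fastq"))
    write_fastq(ecc$control$reads, file.path(dir, "ecc_control.fastq"))
    truth$ecc_treatment <- ecc$treatment$read_truth
    truth$ecc_control <- ecc$control$read_truth
  }
  if (!is.null(wgs)) {
    write_fastq(wgs$reads, file.path(dir, "wgs.fastq"))
    truth$wgs_variants <- wgs$variants
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
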