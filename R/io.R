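#' Read a FASTA file
#' @param path file path.
#' @return named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_chr_seqs(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file (sequences only; qualities are not used downstream)
#' @param path file path.
#' @return named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTQ with constant base quality
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @param quality constant quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  seqs <- as_chr_seqs(seqs)
  # plain 4-line records: the Biostrings fastq writer caps record length at
  # its internal line buffer, which genuine nanopore-length reads exceed
  qual <- strrep(quality, nchar(seqs))
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs),
                           "+", unname(qual)))
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments as PAF
#'
#' Standard 12-column PAF with a `cg:Z:` cigar tag. Coordinates stay 0-based
#' half-open as in the records.
#'
#' @param aln an `mb_alignments` data.frame.
#' @param path output file.
#' @export
write_paf <- function(aln, path) {
  mapq <- ifelse(aln$is_primary, 60L, 0L)
  lines <- paste(aln$query_id, aln$query_len, aln$query_start, aln$query_end,
                 aln$strand, aln$target_id, aln$target_len, aln$target_start,
                 aln$target_end, aln$matches, aln$aln_columns, mapq,
                 paste0("cg:Z:", aln$cigar), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file into an alignment table
#'
#' Accepts 12+ column PAF (as written by [write_paf()] or by external
#' long-read mappers). A `cg:Z:` tag is kept when present; `tp:A:S` tags mark
#' records as secondary, otherwise the best-scoring record per query is primary.
#'
#' @param path PAF file.
#' @return An `mb_alignments` data.frame.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  core <- t(vapply(parts, function(p) p[1:12], character(12)))
  tags <- lapply(parts, function(p) if (length(p) > 12) p[-(1:12)] else character())
  cg <- vapply(tags, function(tg) {
    hit <- grep("^cg:Z:", tg, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, character(1))
  tp <- vapply(tags, function(tg) {
    hit <- grep("^tp:A:", tg, value = TRUE)
    if (length(hit)) sub("^tp:A:", "", hit[1]) else NA_character_
  }, character(1))
  out <- data.frame(query_id = core[, 1], query_len = as.integer(core[, 2]),
                    query_start = as.integer(core[, 3]),
                    query_end = as.integer(core[, 4]), strand = core[, 5],
                    target_id = core[, 6], target_len = as.integer(core[, 7]),
                    target_start = as.integer(core[, 8]),
                    target_end = as.integer(core[, 9]),
                    matches = as.integer(core[, 10]),
                    aln_columns = as.integer(core[, 11]),
                    score = as.numeric(core[, 10]),
                    n_seeds = NA_integer_, cigar = cg,
                    is_primary = NA, stringsAsFactors = FALSE)
  if (all(is.na(tp))) {
    # primary = highest matches per query, ties by (target_id, target_start)
    ord <- order(out$query_id, -out$matches, out$target_id, out$target_start)
    first <- !duplicated(out$query_id[ord])
    out$is_primary <- FALSE
    out$is_primary[ord[first]] <- TRUE
  } else {
    out$is_primary <- tp == "P" | is.na(tp)
  }
  class(out) <- c("mb_alignments", "data.frame")
  out
}

#' Write a TE annotation in the extended BED dialect
#'
#' Columns: chrom, start, end, name, score, strand, family, ltr, where `ltr`
#' encodes element-relative LTR sub-intervals as
#' `"ltr5:start-end;ltr3:start-end"` (0-based half-open).
#'
#' @param ann a TE annotation data.frame (see [simulate_reference()]).
#' @param path output file.
#' @export
write_te_bed <- function(ann, path) {
  ltr <- sprintf("ltr5:%d-%d;ltr3:%d-%d", ann$ltr5_start, ann$ltr5_end,
                 ann$ltr3_start, ann$ltr3_end)
  lines <- paste(ann$chrom, ann$start, ann$end, ann$id,
                 0L, ann$strand, ann$family, ltr, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TE annotation in the extended BED dialect
#' @param path BED file written by [write_te_bed()].
#' @return TE annotation data.frame.
#' @export
read_te_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "id", "score",
                                       "strand", "family", "ltr"))
  m <- regmatches(x$ltr, regexec("ltr5:([0-9]+)-([0-9]+);ltr3:([0-9]+)-([0-9]+)", x$ltr))
  ltr <- t(vapply(m, function(v) as.integer(v[2:5]), integer(4)))
  data.frame(id = x$id, chrom = x$chrom, start = x$start, end = x$end,
             strand = x$strand, family = x$family,
             ltr5_start = ltr[, 1], ltr5_end = ltr[, 2],
             ltr3_start = ltr[, 3], ltr3_end = ltr[, 4],
             stringsAsFactors = FALSE)
}

#' Write variants as a minimal VCF (v4 subset)
#'
#' Emits the 8 mandatory columns (CHROM POS ID REF ALT QUAL FILTER INFO) with
#' depth and allele fraction in INFO. Positions are converted to 1-based.
#'
#' @param variants data.frame with chrom, pos (0-based), ref, alt and
#'   optionally depth, af.
#' @param path output file.
#' @export
write_vcf_min <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- if (!is.null(variants$depth))
      sprintf("DP=%d;AF=%.4f", variants$depth, variants$af) else "."
    writeLines(paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                     variants$alt, ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF (v4 subset)
#'
#' Reads the 8 mandatory columns of any VCF; only SNP records (1 bp REF and
#' ALT) are kept. Positions are converted to 0-based.
#'
#' @param path VCF file.
#' @return data.frame with chrom, pos (0-based), ref, alt, depth, af (NA when
#'   absent from INFO).
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(), af = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  pos <- as.integer(vapply(parts, `[`, character(1), 2)) - 1L
  ref <- vapply(parts, `[`, character(1), 4)
  alt <- vapply(parts, `[`, character(1), 5)
  info <- vapply(parts, function(p) if (length(p) >= 8) p[8] else ".", character(1))
  dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1",
                                        ifelse(grepl("DP=", info), info, NA))))
  af <- suppressWarnings(as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1",
                                        ifelse(grepl("AF=", info), info, NA))))
  keep <- nchar(ref) == 1 & nchar(alt) == 1 & alt != "."
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, depth = dp,
             af = af, stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
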