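# Mapping host flanks to the genome.
#
# The internal aligner is an exact-k-mer-seeded, ungapped aligner intended
# for desk-scale synthetic genomes: every placement reachable through a
# clean k-mer seed is evaluated, mismatches up to a fraction of the flank
# length are allowed, and only flanks with exactly one best-scoring
# placement ("uniquely mapped") are reported. Real-genome runs can instead
# import SAM alignments produced by any external aligner.

#' Build a k-mer genome index
#'
#' Exact positional k-mer index over the forward strand of every contig
#' (reverse-strand hits are found by aligning the reverse complement of a
#' query). Contigs shorter than `k` are kept (they remain visible to
#' exhaustive alignment) but contribute no seeds; a warning is emitted.
#'
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param k Seed k-mer length, in `[11, 31]`.
#' @return An `ltr_genome_index` (external pointer plus contig table).
#' @export
build_index <- function(genome, k = 15L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), sub(" .*", "", names(genome)))
  }
  if (length(genome) == 0) abort("genome is empty")
  if (k < 11 || k > 31) abort("k must lie in [11, 31]")
  short <- nchar(genome) < k
  if (any(short)) {
    warn(paste0("contig(s) shorter than k contribute no seeds: ",
                paste(names(genome)[short], collapse = ", ")))
  }
  structure(list(ptr = cpp_build_index(unname(genome), as.integer(k)),
                 contigs = tibble(contig = names(genome),
                                  length = nchar(genome)),
                 k = as.integer(k)),
            class = "ltr_genome_index")
}

#' @export
print.ltr_genome_index <- function(x, ...) {
  cat(sprintf("# k-mer genome index: %d contigs, %s bp total, k = %d\n",
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
              x$k))
  invisible(x)
}

#' Align flanks and keep unique placements
#'
#' Ungapped seed-and-extend alignment of each flank (both orientations)
#' allowing up to `floor(max_mismatch_frac * length)` mismatches. All
#' best-scoring placements are enumerated; a flank is reported as aligned
#' only when exactly one best placement exists (`n_best == 1`), otherwise
#' its status is `multi_mapped` or `unmapped`. The junction coordinate is
#' the flank edge adjacent to the LTR: flanks are junction-outward, so on
#' the forward strand the junction is the leftmost position and the LTR
#' lies left of the flank; on the reverse strand it is `pos + length` with
#' the LTR to the right.
#'
#' @param flanks Flank table from the chimera stage (`read_id`, `ltr_end`,
#'   `flank_seq`, ...), or a character vector of sequences.
#' @param index An `ltr_genome_index`.
#' @param max_mismatch_frac Allowed mismatch fraction of flank length.
#' @param exhaustive Evaluate every placement instead of seeded candidates
#'   (exact but slow; for small genomes and verification).
#' @return Alignment table: `read_id`, `ltr_end`, `flank_seq`, `contig`,
#'   `pos` (0-based leftmost), `strand`, `score` (matching bases),
#'   `n_best`, `status` (`unique`/`multi_mapped`/`unmapped`), `junction`,
#'   `junction_side`.
#' @export
align_flanks <- function(flanks, index, max_mismatch_frac = 0.06,
                         exhaustive = FALSE) {
  if (is.character(flanks)) {
    flanks <- tibble(read_id = paste0("flank", seq_along(flanks)),
                     ltr_end = NA_character_, flank_seq = flanks)
  }
  if (any(nchar(flanks$flank_seq) < 10))
    abort("flanks must be >= 10 nt")
  if (nrow(flanks) == 0) {
    return(tibble(read_id = character(), ltr_end = character(),
                  flank_seq = character(), contig = character(),
                  pos = integer(), strand = character(), score = integer(),
                  n_best = integer(), status = character(),
                  junction = integer(), junction_side = character()))
  }
  m <- cpp_align_flanks(index$ptr, flanks$flank_seq, max_mismatch_frac,
                        exhaustive)
  L <- nchar(flanks$flank_seq)
  status <- dplyr::case_when(m[, 5] == 0 ~ "unmapped",
                             m[, 5] > 1 ~ "multi_mapped",
                             TRUE ~ "unique")
  uniq <- status == "unique"
  strand <- if_else(m[, 3] == 1L, "+", "-")
  flanks |>
    select(dplyr::any_of(c("read_id", "ltr_end", "flank_seq"))) |>
    mutate(
      contig = if_else(uniq, index$contigs$contig[ifelse(m[, 1] > 0, m[, 1], NA)],
                       NA_character_),
      pos = if_else(uniq, m[, 2], NA_integer_),
      strand = if_else(uniq, strand, NA_character_),
      score = if_else(uniq, L - m[, 4], NA_integer_),
      n_best = m[, 5],
      status = status,
      junction = dplyr::case_when(!uniq ~ NA_integer_,
                                  strand == "+" ~ .data$pos,
                                  TRUE ~ .data$pos + L),
      junction_side = dplyr::case_when(!uniq ~ NA_character_,
                                       strand == "+" ~ "left_of_flank",
                                       TRUE ~ "right_of_flank"))
}

#' Export flank alignments as SAM
#'
#' Writes uniquely mapped flanks as SAM records (MAPQ 60, full-length match
#' CIGAR) and unmapped flanks with the unmapped flag; multi-mapped flanks
#' are omitted. Read names carry the chimera-stage `|ltrend=` tag so the
#' file round-trips through [import_alignments()].
#'
#' @param alignments Alignment table from [align_flanks()].
#' @param index The `ltr_genome_index` used (for `@SQ` header lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
export_sam <- function(alignments, index, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$contigs$contig,
                   index$contigs$length))
  al <- filter(alignments, .data$status != "multi_mapped")
  qname <- sprintf("%s|ltrend=%s", al$read_id, al$ltr_end)
  uniq <- al$status == "unique"
  seq_out <- al$flank_seq
  seq_out[uniq & al$strand == "-"] <- revcomp(seq_out[uniq & al$strand == "-"])
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 qname,
                 if_else(uniq, if_else(al$strand == "-", 16L, 0L), 4L),
                 if_else(uniq, al$contig, "*"),
                 if_else(uniq, al$pos + 1L, 0L),
                 if_else(uniq, 60L, 0L),
                 if_else(uniq, paste0(nchar(al$flank_seq), "M"), "*"),
                 seq_out,
                 strrep("F", nchar(al$flank_seq)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Import external flank alignments from SAM/BAM
#'
#' Route for real-genome runs: align the chimera-stage flank FASTA (see
#' [write_flanks()]) with any external aligner and import the result.
#' Records with mapping quality 0 or secondary/supplementary flags are
#' excluded (the portable uniqueness proxy); coordinates are converted to
#' 0-based and the junction is derived from the `|ltrend=` read-name tag
#' and the FLAG strand bit. Records without the tag are skipped and
#' counted.
#'
#' @param sam_path SAM or BAM file.
#' @return Alignment table in the [align_flanks()] layout (unique records
#'   only); attribute `"metrics"` records exclusions.
#' @export
import_alignments <- function(sam_path) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_all <- length(res$qname)
  mapped <- !is.na(res$pos)
  usable <- mapped & res$mapq > 0
  has_tag <- grepl("\\|ltrend=(five_prime|three_prime)", res$qname)
  keep <- usable & has_tag
  L <- Biostrings::width(res$seq)[keep]
  strand <- as.character(res$strand)[keep]
  seqs <- as.character(res$seq)[keep]
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])  # back to flank space
  pos0 <- res$pos[keep] - 1L
  out <- tibble(
    read_id = sub("\\|ltrend=.*$", "", res$qname[keep]),
    ltr_end = sub(".*\\|ltrend=(five_prime|three_prime).*", "\\1",
                  res$qname[keep]),
    flank_seq = seqs,
    contig = as.character(res$rname)[keep],
    pos = pos0,
    strand = strand,
    score = NA_integer_,
    n_best = 1L,
    status = "unique",
    junction = if_else(strand == "+", pos0, pos0 + L),
    junction_side = if_else(strand == "+", "left_of_flank",
                            "right_of_flank"))
  attr(out, "metrics") <- list(
    n_records = n_all,
    n_excluded_nonunique = sum(mapped & !usable),
    n_unmapped = sum(!mapped),
    n_missing_tag = sum(usable & !has_tag))
  out
}
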