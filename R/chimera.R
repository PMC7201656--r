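# LTR-host chimeric read detection.
#
# Reads are screened with 20-bp terminal LTR "baits" (start and end of each
# LTR consensus, forward and reverse complement) by ungapped sliding-window
# identity; qualifying reads are split at the bait boundary into the host
# flank, the linker remnant is stripped, and flanks homologous to
# retrovirus-internal sequence (LTR-gag / LTR-env amplicons) are removed.
#
# Flank orientation convention: extracted flanks read 5'->3' AWAY from the
# LTR junction, so the junction sits at the flank's first base and the
# ligated linker (when sequenced through) is always a flank suffix.

#' Construct a bait set
#'
#' Default baits are the first and last `bait_len` bases of every LTR
#' subtype consensus; `five_prime` baits recognise host|LTR-start junctions
#' and `three_prime` baits LTR-end|host junctions. Custom baits can be
#' supplied as a data frame (`bait_name`, `ltr_end`, `seq`).
#'
#' @param baits Optional data frame of custom baits.
#' @param elements Sequence set from [hml2_elements()] for the defaults.
#' @param bait_len Bait length (bp).
#' @param min_identity Minimum sliding-window identity in `(0.5, 1]`.
#' @return An `ltr_baitset` tibble with attributes `bait_len`,
#'   `min_identity`.
#' @export
bait_set <- function(baits = NULL, elements = hml2_elements(),
                     bait_len = 20L, min_identity = 0.90) {
  if (min_identity <= 0.5 || min_identity > 1)
    abort("min_identity must lie in (0.5, 1]")
  if (is.null(baits)) {
    baits <- purrr::map_dfr(names(elements$ltr), function(s) {
      ltr <- elements$ltr[[s]]
      tibble(bait_name = paste0(s, c("_start", "_end")),
             ltr_end = c("five_prime", "three_prime"),
             seq = c(substr(ltr, 1L, bait_len),
                     substr(ltr, nchar(ltr) - bait_len + 1L, nchar(ltr))))
    })
  } else {
    baits <- as_tibble(baits)
  }
  if (any(nchar(baits$seq) != bait_len))
    abort("all baits must have length bait_len")
  structure(baits, class = c("ltr_baitset", class(tibble())),
            bait_len = as.integer(bait_len), min_identity = min_identity)
}

#' Find the best bait window in each read
#'
#' Evaluates every bait and its reverse complement at every read offset by
#' ungapped identity (matching positions / bait length; `N` never matches)
#' and keeps the best window with identity >= `min_identity`. Ties are
#' broken toward fewer mismatches, then the smaller offset, then bait
#' declaration order (all forward baits before all reverse-complement
#' baits). Reads shorter than the bait are counted as too short.
#'
#' @param reads Read table (`read_id`, `seq`, `qual`) from [merge_pairs()].
#' @param baitset An `ltr_baitset`.
#' @return Hit table (`read_id`, `seq`, `qual`, `bait_name`, `ltr_end`,
#'   `orientation`, `read_offset`, `identity`); attribute `"metrics"`
#'   records totals.
#' @export
match_baits <- function(reads, baitset) {
  bl <- attr(baitset, "bait_len")
  min_id <- attr(baitset, "min_identity")
  max_mm <- as.integer(floor(bl * (1 - min_id) + 1e-9))
  scan_seqs <- c(baitset$seq, revcomp(baitset$seq))
  scan_meta <- tibble(
    bait_name = rep(baitset$bait_name, 2L),
    ltr_end = rep(baitset$ltr_end, 2L),
    orientation = rep(c("+", "-"), each = nrow(baitset)))

  long_enough <- nchar(reads$seq) >= bl
  sub <- reads[long_enough, ]
  if (nrow(sub) == 0) {
    res <- tibble(read_id = character(), seq = character(),
                  qual = character(), bait_name = character(),
                  ltr_end = character(), orientation = character(),
                  read_offset = integer(), identity = numeric())
    attr(res, "metrics") <- list(n_in = nrow(reads),
                                 n_too_short = sum(!long_enough),
                                 n_hit = 0L)
    return(res)
  }
  hits <- cpp_scan_baits(sub$seq, scan_seqs, max_mm)
  has <- hits[, 1] > 0
  res <- sub[has, ] |>
    bind_cols(scan_meta[hits[has, 1], ]) |>
    mutate(read_offset = hits[has, 2],
           identity = (bl - hits[has, 3]) / bl)
  attr(res, "metrics") <- list(n_in = nrow(reads),
                               n_too_short = sum(!long_enough),
                               n_hit = nrow(res))
  res
}

#' Extract the host flank from bait hits
#'
#' Splits each read at the bait boundary on the host side of the LTR end
#' and discards the LTR-side bases. Flanks are normalised to read 5'->3'
#' away from the junction regardless of the matched orientation, so a read
#' and its reverse complement yield the same flank. Zero-length flanks are
#' dropped and counted.
#'
#' @param hits Hit table from [match_baits()].
#' @param bait_len Bait length (must match the bait set used).
#' @return Hit table with `flank_seq`, `flank_qual` columns; attribute
#'   `"metrics"` records the drop count.
#' @export
extract_flanks <- function(hits, bait_len = 20L) {
  if (nrow(hits) == 0) {
    res <- mutate(hits, flank_seq = character(), flank_qual = character())
    attr(res, "metrics") <- list(n_in = 0L, n_empty_flank = 0L)
    return(res)
  }
  len <- nchar(hits$seq)
  off <- hits$read_offset            # 0-based bait start
  # "prefix" = read part before the bait, "suffix" = after the bait.
  pre_seq <- substr(hits$seq, 1L, off)
  pre_q <- substr(hits$qual, 1L, off)
  suf_seq <- substr(hits$seq, off + bait_len + 1L, len)
  suf_q <- substr(hits$qual, off + bait_len + 1L, len)
  # five_prime "+": host precedes the LTR start; flip to junction-outward.
  # three_prime "+": host follows the LTR end, already junction-outward.
  # On "-" matches the molecule is reverse-complemented, so the roles swap.
  take_pre <- (hits$ltr_end == "five_prime" & hits$orientation == "+") |
    (hits$ltr_end == "three_prime" & hits$orientation == "-")
  flank_seq <- flank_qual <- character(nrow(hits))
  flank_seq[take_pre] <- revcomp(pre_seq[take_pre])
  flank_qual[take_pre] <- stringi::stri_reverse(pre_q[take_pre])
  flank_seq[!take_pre] <- suf_seq[!take_pre]
  flank_qual[!take_pre] <- suf_q[!take_pre]
  res <- hits |>
    mutate(flank_seq = flank_seq, flank_qual = flank_qual) |>
    filter(nchar(.data$flank_seq) >= 1L)
  attr(res, "metrics") <- list(n_in = nrow(hits),
                               n_empty_flank = nrow(hits) - nrow(res))
  res
}

#' Strip the linker remnant from flanks
#'
#' Removes the best suffix match of each flank against the linker: the
#' longest suffix/prefix overlap of length >= `min_overlap` with at most
#' `max_mismatch_ratio` mismatches (a partial, read-through-truncated
#' linker matches as a linker prefix). Flanks shorter than `min_flank`
#' after stripping are abandoned and counted.
#'
#' @param hits Flank table from [extract_flanks()].
#' @param linker_seq Linker sequence (>= 8 nt).
#' @param min_flank Minimum surviving flank length.
#' @param min_overlap Minimum linker overlap to strip.
#' @param max_mismatch_ratio Maximum mismatch fraction in the overlap.
#' @return Flank table with stripped `flank_seq`/`flank_qual`; attribute
#'   `"metrics"` records stripped and dropped counts.
#' @export
strip_linker <- function(hits, linker_seq, min_flank = 10L,
                         min_overlap = 6L, max_mismatch_ratio = 0.10) {
  if (nchar(linker_seq) < 8) abort("linker_seq must be >= 8 nt")
  if (nrow(hits) == 0) {
    attr(hits, "metrics") <- list(n_in = 0L, n_stripped = 0L,
                                  n_dropped = 0L)
    return(hits)
  }
  L <- nchar(hits$flank_seq)
  lk <- nchar(linker_seq)
  cut <- integer(nrow(hits))
  todo <- rep(TRUE, nrow(hits))
  o_max <- min(lk, max(L))
  for (o in if (o_max >= min_overlap) seq(o_max, min_overlap) else integer()) {
    idx <- which(todo & L >= o)
    if (length(idx) == 0) next
    mm <- mismatch_count(substr(hits$flank_seq[idx], L[idx] - o + 1L, L[idx]),
                         rep(substr(linker_seq, 1L, o), length(idx)))
    ok <- mm <= floor(max_mismatch_ratio * o)
    cut[idx[ok]] <- o
    todo[idx[ok]] <- FALSE
  }
  res <- hits |>
    mutate(flank_seq = substr(.data$flank_seq, 1L, L - cut),
           flank_qual = substr(.data$flank_qual, 1L, L - cut))
  keep <- nchar(res$flank_seq) >= min_flank
  out <- res[keep, ]
  attr(out, "metrics") <- list(n_in = nrow(hits),
                               n_stripped = sum(cut > 0),
                               n_dropped = sum(!keep))
  out
}

#' Remove flanks homologous to retrovirus-internal sequence
#'
#' Drops any flank with a local ungapped match to any catalogued HML-2
#' sequence at >= `min_identity` over >= `min_len` nt (operationally: some
#' `min_len`-base window with at least `ceiling(min_identity * min_len)`
#' matches on a k-mer-seeded diagonal). These are the LTR-gag / LTR-env
#' amplicons arising from proviral internal junctions.
#'
#' @param hits Flank table.
#' @param hervk_seqs Character vector (or `DNAStringSet`) of HML-2
#'   reference sequences (LTR consensus set plus internal sequence).
#' @param min_identity Identity threshold.
#' @param min_len Minimum local match length.
#' @param seed_k Seed k-mer length for candidate diagonals.
#' @return Surviving flank table; attribute `"metrics"` records removals.
#' @export
filter_internal_hervk <- function(hits, hervk_seqs, min_identity = 0.90,
                                  min_len = 20L, seed_k = 11L) {
  hervk_seqs <- as.character(hervk_seqs)
  if (length(hervk_seqs) == 0) abort("hervk_seqs must be non-empty")
  if (nrow(hits) == 0) {
    attr(hits, "metrics") <- list(n_in = 0L, n_internal = 0L)
    return(hits)
  }
  bad <- cpp_local_match(hits$flank_seq, hervk_seqs, seed_k, min_len,
                         as.integer(ceiling(min_identity * min_len)))
  res <- hits[!bad, ]
  attr(res, "metrics") <- list(n_in = nrow(hits), n_internal = sum(bad))
  res
}

#' Run the full chimera stage
#'
#' Bait matching, flank extraction, linker stripping and the internal-HML-2
#' filter in sequence. Every survivor has flank length >= `min_flank` and
#' bait identity >= the bait set's `min_identity`.
#'
#' @param reads Read table from [merge_pairs()] / [prep_reads()].
#' @param baitset An `ltr_baitset`.
#' @param linker_seq Linker sequence.
#' @param hervk_seqs HML-2 sequence set for the internal filter.
#' @param min_flank Minimum flank length after linker stripping.
#' @return Flank table; attribute `"metrics"` aggregates per-step metrics.
#' @export
find_chimeras <- function(reads, baitset, linker_seq, hervk_seqs,
                          min_flank = 10L) {
  hits <- match_baits(reads, baitset)
  fl <- extract_flanks(hits, attr(baitset, "bait_len"))
  st <- strip_linker(fl, linker_seq, min_flank = min_flank)
  out <- filter_internal_hervk(st, hervk_seqs)
  attr(out, "metrics") <- list(bait = attr(hits, "metrics"),
                               flank = attr(fl, "metrics"),
                               linker = attr(st, "metrics"),
                               internal = attr(out, "metrics"))
  out
}

#' Write flanks as FASTA with chimera-stage tags
#'
#' Sequence ids carry the chimera-stage tags (`|ltrend=`, `|ident=`)
#' required by [import_alignments()] after external alignment.
#'
#' @param hits Flank table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flanks <- function(hits, path) {
  x <- Biostrings::DNAStringSet(hits$flank_seq)
  names(x) <- sprintf("%s|ltrend=%s|ident=%.3f", hits$read_id, hits$ltr_end,
                      hits$identity)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
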