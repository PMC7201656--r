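# Read preparation: sliding-window quality trimming, PCR-duplicate removal
# and overlap merging of read pairs. The stage order follows the enrichment
# protocol's pipeline (deduplicate before merging); `dedup_first = FALSE`
# swaps it for the more common merge-then-dedup order.

#' Sliding-window quality trimming of read pairs
#'
#' Each mate is cut at the start of the first sliding window (length
#' `window`, step 1) whose mean Phred quality falls below `mean_q`; a pair
#' is dropped when either trimmed mate is shorter than `min_len`.
#'
#' @param pairs Pair table (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param window Window length (>= 1).
#' @param mean_q Mean-quality threshold.
#' @param min_len Minimum surviving mate length.
#' @param phred_offset Quality encoding offset (33 = Sanger).
#' @return Trimmed pair table; attribute `"metrics"` records input and
#'   dropped pair counts.
#' @export
quality_trim <- function(pairs, window = 4L, mean_q = 15, min_len = 36L,
                         phred_offset = 33L) {
  if (window < 1) abort("window must be >= 1")
  if (nrow(pairs) == 0) return(pairs)
  k1 <- cpp_quality_keep_len(pairs$qual1, window, mean_q, phred_offset)
  k2 <- cpp_quality_keep_len(pairs$qual2, window, mean_q, phred_offset)
  out <- pairs |>
    mutate(seq1 = substr(.data$seq1, 1L, k1),
           qual1 = substr(.data$qual1, 1L, k1),
           seq2 = substr(.data$seq2, 1L, k2),
           qual2 = substr(.data$qual2, 1L, k2))
  keep <- k1 >= min_len & k2 >= min_len
  res <- out[keep, ]
  attr(res, "metrics") <- list(n_in = nrow(pairs),
                               n_dropped = sum(!keep))
  res
}

mean_qual_chr <- function(qual, phred_offset = 33L) {
  vapply(qual, function(q) {
    if (nchar(q) == 0) return(0)
    mean(utf8ToInt(q)) - phred_offset
  }, numeric(1), USE.NAMES = FALSE)
}

#' Remove PCR duplicates from a pair table
#'
#' Pairs with identical `(seq1, seq2)` are collapsed to one representative:
#' the pair with the highest mean quality over both mates wins, ties going
#' to the first encountered. Duplication is defined on the sequence level
#' (pre-alignment), matching a pipeline that deduplicates before mapping.
#'
#' @param pairs Pair table.
#' @param phred_offset Quality encoding offset.
#' @return Deduplicated pair table in first-occurrence order; attribute
#'   `"metrics"` records the number of removed duplicates.
#' @export
dedup_pairs <- function(pairs, phred_offset = 33L) {
  if (nrow(pairs) == 0) {
    attr(pairs, "metrics") <- list(n_in = 0L, n_duplicates = 0L)
    return(pairs)
  }
  key <- paste(pairs$seq1, pairs$seq2, sep = "\x1f")
  dup_key <- unique(key[duplicated(key)])
  if (length(dup_key) == 0) {
    attr(pairs, "metrics") <- list(n_in = nrow(pairs), n_duplicates = 0L)
    return(pairs)
  }
  in_dup <- key %in% dup_key
  # among duplicated groups keep the highest-mean-quality pair (ties: first)
  mq <- numeric(nrow(pairs))
  mq[in_dup] <- mean_qual_chr(paste0(pairs$qual1[in_dup],
                                     pairs$qual2[in_dup]), phred_offset)
  ord <- order(match(key, key), -mq)  # stable within key by quality
  keep_idx <- sort(ord[!duplicated(key[ord])])
  res <- pairs[keep_idx, ]
  attr(res, "metrics") <- list(n_in = nrow(pairs),
                               n_duplicates = nrow(pairs) - length(keep_idx))
  res
}

#' Merge overlapping read pairs
#'
#' Finds the best overlap between mate 1 and the reverse complement of
#' mate 2 (lowest mismatch ratio, ties to the longer overlap) with a length
#' of at least `min_overlap` and mismatch ratio <= `max_mismatch_ratio`.
#' Qualifying
#' pairs are merged into one read (disagreeing overlap bases resolved
#' toward the higher-quality mate); pairs without a qualifying overlap pass
#' through as two single reads, so both merged and single reads reach the
#' chimera stage.
#'
#' @param pairs Pair table.
#' @param min_overlap Minimum overlap length (>= 5).
#' @param max_mismatch_ratio Maximum mismatch fraction inside the overlap.
#' @return Read table (`read_id`, `seq`, `qual`, `merged`); unmerged mates
#'   get `/1` and `/2` name suffixes. Attribute `"metrics"` records the
#'   merged fraction.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_ratio = 0.1) {
  if (min_overlap < 5) abort("min_overlap must be >= 5")
  if (nrow(pairs) == 0) {
    return(tibble(read_id = character(), seq = character(),
                  qual = character(), merged = logical()))
  }
  rc2 <- revcomp(pairs$seq2)
  q2r <- stringi::stri_reverse(pairs$qual2)
  ov <- cpp_best_overlap(pairs$seq1, rc2, min_overlap, max_mismatch_ratio)
  o <- ov[, 1]; mm <- ov[, 2]
  is_merged <- o > 0
  l1 <- nchar(pairs$seq1)

  m_seq <- m_qual <- character(sum(is_merged))
  mi <- which(is_merged)
  # agreement case: overlap taken from mate 2 (identical bases)
  m_seq <- paste0(substr(pairs$seq1[mi], 1L, l1[mi] - o[mi]), rc2[mi])
  m_qual <- paste0(substr(pairs$qual1[mi], 1L, l1[mi] - o[mi]), q2r[mi])
  fix <- mi[mm[mi] > 0]
  if (length(fix) > 0) {
    for (w in seq_along(fix)) {
      i <- fix[w]
      oo <- o[i]
      a <- strsplit(substr(pairs$seq1[i], l1[i] - oo + 1L, l1[i]), "")[[1]]
      b <- strsplit(substr(rc2[i], 1L, oo), "")[[1]]
      qa <- utf8ToInt(substr(pairs$qual1[i], l1[i] - oo + 1L, l1[i]))
      qb <- utf8ToInt(substr(q2r[i], 1L, oo))
      pick_a <- a != b & qa > qb
      res_b <- b; res_b[pick_a] <- a[pick_a]
      res_q <- intToUtf8(pmax(qa, qb), multiple = FALSE)
      j <- match(i, mi)
      m_seq[j] <- paste0(substr(pairs$seq1[i], 1L, l1[i] - oo),
                         paste(res_b, collapse = ""),
                         substr(rc2[i], oo + 1L, nchar(rc2[i])))
      m_qual[j] <- paste0(substr(pairs$qual1[i], 1L, l1[i] - oo), res_q,
                          substr(q2r[i], oo + 1L, nchar(q2r[i])))
    }
  }
  merged_tbl <- tibble(read_id = pairs$read_id[mi], seq = m_seq,
                       qual = m_qual, merged = TRUE)
  ui <- which(!is_merged)
  single_tbl <- if (length(ui) > 0) {
    tibble(
      read_id = c(paste0(pairs$read_id[ui], "/1"),
                  paste0(pairs$read_id[ui], "/2")),
      seq = c(pairs$seq1[ui], pairs$seq2[ui]),
      qual = c(pairs$qual1[ui], pairs$qual2[ui]),
      merged = FALSE)
  } else {
    tibble(read_id = character(), seq = character(), qual = character(),
           merged = logical())
  }
  res <- bind_rows(merged_tbl, single_tbl)
  attr(res, "metrics") <- list(n_pairs = nrow(pairs),
                               n_merged = length(mi),
                               merged_fraction = length(mi) / nrow(pairs))
  res
}

#' Run the full read-preparation stage
#'
#' Quality trim, then (by default) deduplicate before merging.
#'
#' @param pairs Pair table.
#' @param dedup_first Deduplicate before merging (the enrichment protocol's
#'   printed order); `FALSE` merges first.
#' @param trim,merge Named lists of arguments for [quality_trim()] and
#'   [merge_pairs()].
#' @return Read table as from [merge_pairs()], with combined metrics.
#' @export
prep_reads <- function(pairs, dedup_first = TRUE,
                       trim = list(), merge = list()) {
  trimmed <- do.call(quality_trim, c(list(pairs), trim))
  if (dedup_first) {
    dd <- dedup_pairs(trimmed)
    reads <- do.call(merge_pairs, c(list(dd), merge))
  } else {
    merged <- do.call(merge_pairs, c(list(trimmed), merge))
    # sequence-level dedup on the merged representation
    key <- paste(merged$seq, merged$merged, sep = "\x1f")
    reads <- merged[!duplicated(key), ]
    dd <- NULL
  }
  attr(reads, "metrics") <- list(
    trim = attr(trimmed, "metrics"),
    dedup = if (dedup_first) attr(dd, "metrics") else NULL,
    merge = attr(reads, "metrics"))
  reads
}
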