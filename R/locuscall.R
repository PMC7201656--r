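# Locus calling: catalog assignment within a 10-nt window, CPM
# quantification with the detection filter, novel-locus discovery by
# junction clustering with the > 2 kb rule, and target-site-duplication
# classification of novel candidates.

# Distance from a junction boundary coordinate to a catalog interval
# [start, end): 0 when start <= j <= end (both edges are boundary
# coordinates), otherwise the distance to the nearer edge.
junction_distance <- function(j, start, end) {
  pmax(start - j, j - end, 0L)
}

#' Assign unique flank alignments to catalog loci
#'
#' Each alignment's junction coordinate is tested against every catalog
#' record expanded by `window_nt`; a junction within the window increments
#' exactly one locus (the nearest edge wins; an exact tie goes to the
#' lower-coordinate locus and is counted). Alignments matching no window
#' are returned as unassigned.
#'
#' @param alignments Alignment table (uniquely mapped rows are used).
#' @param catalog A `hervk_catalog`.
#' @param window_nt Assignment window in nucleotides.
#' @return List: `counts` (tibble `locus_id`, `count`, zero rows included),
#'   `assigned` (alignment rows + `locus_id`), `unassigned` (alignment
#'   rows), `n_ties`.
#' @export
assign_to_catalog <- function(alignments, catalog, window_nt = 10L) {
  al <- filter(alignments, .data$status == "unique")
  if (nrow(al) == 0) {
    return(list(counts = tibble(locus_id = catalog$locus_id, count = 0L),
                assigned = mutate(al, locus_id = character()),
                unassigned = al, n_ties = 0L))
  }
  cat_tbl <- as_tibble(catalog) |>
    mutate(.row = row_number())
  pairs <- purrr::map_dfr(unique(al$contig), function(ctg) {
    ai <- which(al$contig == ctg)
    ci <- which(cat_tbl$contig == ctg)
    if (length(ci) == 0) return(tibble())
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = al$junction[ai] + 1L, width = 1L),
      IRanges::IRanges(start = cat_tbl$start[ci] + 1L - window_nt,
                       end = cat_tbl$end[ci] + window_nt + 1L))
    if (length(ov) == 0) return(tibble())
    a <- ai[S4Vectors::queryHits(ov)]
    c_ <- ci[S4Vectors::subjectHits(ov)]
    tibble(a = a, cat_row = c_,
           dist = junction_distance(al$junction[a],
                                    cat_tbl$start[c_], cat_tbl$end[c_]))
  }) |>
    filter(.data$dist <= window_nt)

  if (nrow(pairs) == 0) {
    return(list(counts = tibble(locus_id = catalog$locus_id, count = 0L),
                assigned = al[0, ] |> mutate(locus_id = character()),
                unassigned = al, n_ties = 0L))
  }
  best <- pairs |>
    left_join(select(cat_tbl, ".row", "start", "locus_id"),
              by = c(cat_row = ".row")) |>
    group_by(.data$a) |>
    arrange(.data$dist, .data$start, .by_group = TRUE) |>
    summarise(locus_id = first(.data$locus_id),
              tie = sum(.data$dist == first(.data$dist)) > 1L)
  assigned <- al[best$a, ] |> mutate(locus_id = best$locus_id)
  counts <- tibble(locus_id = catalog$locus_id) |>
    left_join(count(assigned, .data$locus_id, name = "count"),
              by = "locus_id") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  list(counts = counts,
       assigned = assigned,
       unassigned = al[setdiff(seq_len(nrow(al)), best$a), ],
       n_ties = sum(best$tie))
}

#' Quantify loci as counts per million
#'
#' CPM is `count / library_size * 1e6` with the library size defined as the
#' number of uniquely mapped flanks after all filters (making CPM invariant
#' to raw sequencing depth). A locus is `detected` with at least one count
#' and `detected_filtered` at CPM >= `cpm_min` (a locus at exactly the
#' threshold passes).
#'
#' @param counts Tibble `locus_id`, `count` from [assign_to_catalog()].
#' @param library_size Uniquely mapped flank count (> 0).
#' @param cpm_min CPM detection threshold.
#' @param sample_id Sample label.
#' @return Quantification tibble: `sample_id`, `locus_id`, `count`,
#'   `library_size`, `cpm`, `detected`, `detected_filtered`.
#' @export
quantify <- function(counts, library_size, cpm_min = 50,
                     sample_id = "sample") {
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0)
    abort("library_size must be a single positive count")
  counts |>
    mutate(sample_id = sample_id,
           library_size = as.integer(library_size),
           cpm = .data$count / library_size * 1e6,
           detected = .data$count >= 1L,
           detected_filtered = .data$count >= 1L & .data$cpm >= cpm_min) |>
    relocate("sample_id")
}

#' Discover novel loci from unassigned junctions
#'
#' Junctions are clustered per contig by single linkage at `cluster_gap`;
#' clusters with at least `min_reads` reads whose span lies more than
#' `min_novel_dist` from every catalog record become novel-locus
#' candidates. Clusters between `window_nt` and `min_novel_dist` of a
#' record are labelled `ambiguous` and excluded from novel calls.
#'
#' @param unassigned Unassigned alignment rows from [assign_to_catalog()].
#' @param catalog A `hervk_catalog`.
#' @param min_novel_dist Minimum distance (nt) from any catalog record.
#' @param cluster_gap Single-linkage gap (nt).
#' @param min_reads Minimum supporting reads per cluster.
#' @param window_nt Catalog assignment window (for the `near_known` label).
#' @return Tibble of clusters: `cluster_id`, `contig`, `start`, `end`
#'   (junction span), `n_reads`, junction-side and LTR-end support counts,
#'   `dist_to_catalog`, `status` (`candidate`/`ambiguous`/`near_known`)
#'   and a `members` list-column of the member junctions.
#' @export
discover_novel <- function(unassigned, catalog, min_novel_dist = 2000L,
                           cluster_gap = 50L, min_reads = 2L,
                           window_nt = 10L) {
  if (nrow(unassigned) == 0) {
    return(tibble(cluster_id = character(), contig = character(),
                  start = integer(), end = integer(), n_reads = integer(),
                  n_left = integer(), n_right = integer(),
                  n_five_prime = integer(), n_three_prime = integer(),
                  dist_to_catalog = numeric(), status = character(),
                  members = list()))
  }
  cl <- unassigned |>
    group_by(.data$contig) |>
    arrange(.data$junction, .by_group = TRUE) |>
    mutate(new_cluster = c(TRUE, diff(.data$junction) > cluster_gap),
           cluster = cumsum(.data$new_cluster)) |>
    ungroup()
  clusters <- cl |>
    group_by(.data$contig, .data$cluster) |>
    summarise(start = min(.data$junction), end = max(.data$junction),
              n_reads = n(),
              n_left = sum(.data$junction_side == "left_of_flank"),
              n_right = sum(.data$junction_side == "right_of_flank"),
              n_five_prime = sum(.data$ltr_end %in% "five_prime"),
              n_three_prime = sum(.data$ltr_end %in% "three_prime"),
              members = list(dplyr::pick("junction", "junction_side",
                                         "ltr_end", "read_id")),
              .groups = "drop") |>
    filter(.data$n_reads >= min_reads)
  if (nrow(clusters) == 0) return(clusters |> mutate(cluster_id = character(),
                                                     dist_to_catalog = numeric(),
                                                     status = character()))
  cat_tbl <- as_tibble(catalog)
  clusters <- clusters |>
    mutate(dist_to_catalog = purrr::map2_dbl(.data$contig, row_number(),
      function(ctg, i) {
        sub <- cat_tbl[cat_tbl$contig == ctg, ]
        if (nrow(sub) == 0) return(Inf)
        min(pmax(sub$start - clusters$end[i], clusters$start[i] - sub$end, 0L))
      }),
      status = dplyr::case_when(
        .data$dist_to_catalog > min_novel_dist ~ "candidate",
        .data$dist_to_catalog <= window_nt ~ "near_known",
        TRUE ~ "ambiguous"),
      cluster_id = sprintf("novel_%s_%d", .data$contig, .data$start)) |>
    select("cluster_id", "contig", "start", "end", "n_reads", "n_left",
           "n_right", "n_five_prime", "n_three_prime", "dist_to_catalog",
           "status", "members")
  clusters
}

mode_int <- function(x) {
  t <- sort(table(x), decreasing = TRUE)
  as.integer(names(t)[1])
}

#' Classify novel candidates via the target-site duplication
#'
#' A candidate supported by junctions on both flank sides whose
#' right-of-flank and left-of-flank junction positions differ by 1 to
#' `max_tsd` bases records that interval as the target-site duplication
#' and is classified `novel_non_reference` (the TSD is reported 1-based
#' inclusive). Otherwise, when an annotated-but-uncatalogued LTR interval
#' track is supplied and overlaps the candidate (expanded by `window_nt`),
#' the candidate is `novel_reference` and takes the annotated element's
#' interval (single-ended clusters at the two ends of one element thereby
#' merge into one call). Anything else stays `ambiguous`.
#'
#' @param candidates Cluster table from [discover_novel()] (only
#'   `status == "candidate"` rows are classified).
#' @param max_tsd Maximum TSD length (bp).
#' @param ltr_annotation Optional tibble (`contig`, `start`, `end`) of
#'   annotated LTR intervals in reference coordinates.
#' @param window_nt Overlap slack for the annotation match.
#' @return Tibble of novel calls: `novel_id`, `contig`, `start`, `end`,
#'   `classification`, `tsd_start`, `tsd_end` (1-based inclusive),
#'   `tsd_len`, `supporting_reads`, `n_five_prime`, `n_three_prime`.
#' @export
classify_novel <- function(candidates, max_tsd = 10L, ltr_annotation = NULL,
                           window_nt = 10L) {
  cand <- filter(candidates, .data$status == "candidate")
  if (nrow(cand) == 0) {
    return(tibble(novel_id = character(), contig = character(),
                  start = integer(), end = integer(),
                  classification = character(), tsd_start = integer(),
                  tsd_end = integer(), tsd_len = integer(),
                  supporting_reads = integer(), n_five_prime = integer(),
                  n_three_prime = integer()))
  }
  out <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    mem <- cand$members[[i]]
    jl <- mem$junction[mem$junction_side == "left_of_flank"]
    jr <- mem$junction[mem$junction_side == "right_of_flank"]
    res <- tibble(novel_id = cand$cluster_id[i], contig = cand$contig[i],
                  start = cand$start[i], end = cand$end[i],
                  classification = "ambiguous",
                  tsd_start = NA_integer_, tsd_end = NA_integer_,
                  tsd_len = NA_integer_,
                  supporting_reads = cand$n_reads[i],
                  n_five_prime = cand$n_five_prime[i],
                  n_three_prime = cand$n_three_prime[i],
                  .ann_row = NA_integer_)
    if (length(jl) > 0 && length(jr) > 0) {
      d <- mode_int(jr) - mode_int(jl)
      if (d >= 1 && d <= max_tsd) {
        res$classification <- "novel_non_reference"
        res$tsd_start <- mode_int(jl) + 1L   # 1-based inclusive footprint
        res$tsd_end <- mode_int(jr)
        res$tsd_len <- d
        return(res)
      }
    }
    if (!is.null(ltr_annotation)) {
      ann <- ltr_annotation[ltr_annotation$contig == cand$contig[i], ,
                            drop = FALSE]
      if (nrow(ann) > 0) {
        hit <- which(ann$start <= cand$end[i] + window_nt &
                       ann$end >= cand$start[i] - window_nt)
        if (length(hit) > 0) {
          h <- hit[1]
          res$classification <- "novel_reference"
          res$start <- ann$start[h]
          res$end <- ann$end[h]
          res$.ann_row <- which(ltr_annotation$contig == cand$contig[i])[h]
          return(res)
        }
      }
    }
    res
  })
  # merge single-ended clusters matched to the same annotated element
  merged <- out |>
    group_by(.data$classification, .data$contig, .data$.ann_row) |>
    mutate(.grp = dplyr::cur_group_id()) |>
    ungroup()
  ann_grp <- merged$classification == "novel_reference" & !is.na(merged$.ann_row)
  if (any(ann_grp)) {
    fused <- merged[ann_grp, ] |>
      group_by(.data$contig, .data$.ann_row) |>
      summarise(novel_id = first(.data$novel_id),
                start = first(.data$start), end = first(.data$end),
                classification = "novel_reference",
                tsd_start = NA_integer_, tsd_end = NA_integer_,
                tsd_len = NA_integer_,
                supporting_reads = sum(.data$supporting_reads),
                n_five_prime = sum(.data$n_five_prime),
                n_three_prime = sum(.data$n_three_prime),
                .groups = "drop") |>
      select(-".ann_row")
    out <- bind_rows(select(merged[!ann_grp, ], -".ann_row", -".grp"),
                     fused) |>
      arrange(.data$contig, .data$start)
  } else {
    out <- select(out, -".ann_row") |> arrange(.data$contig, .data$start)
  }
  out
}

#' Saturation analysis by nested subsampling
#'
#' Draws nested subsamples of the raw read pairs (each smaller depth a
#' subset of every larger one, from one seeded shuffle), runs each through
#' the full per-sample pipeline and reports detected-locus counts, both
#' unfiltered and CPM-filtered. Depths exceeding the available reads are
#' reported as `NA` with a warning.
#'
#' @param pairs Raw pair table for one sample.
#' @param depths Ascending read-pair depths.
#' @param catalog A `hervk_catalog`.
#' @param index An `ltr_genome_index`.
#' @param config Pipeline configuration from [pipeline_config()].
#' @param seed Integer seed for the shuffle.
#' @return `ltr_saturation` tibble: `depth`, `n_used`, `library_size`,
#'   `detected`, `detected_filtered`.
#' @export
saturation <- function(pairs, depths, catalog, index,
                       config = pipeline_config(), seed = 1L) {
  if (is.unsorted(depths)) abort("depths must be ascending")
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  rows <- purrr::map_dfr(depths, function(d) {
    if (d > nrow(pairs)) {
      warn(sprintf("depth %d exceeds available reads (%d); reported as NA",
                   d, nrow(pairs)))
      return(tibble(depth = d, n_used = NA_integer_,
                    library_size = NA_integer_, detected = NA_integer_,
                    detected_filtered = NA_integer_))
    }
    if (d == 0) {
      return(tibble(depth = 0L, n_used = 0L, library_size = 0L,
                    detected = 0L, detected_filtered = 0L))
    }
    sub <- pairs[sort(ord[seq_len(d)]), ]
    q <- process_sample(sub, catalog, index, config)$quant
    tibble(depth = d, n_used = d,
           library_size = q$library_size[1],
           detected = sum(q$detected),
           detected_filtered = sum(q$detected_filtered))
  })
  structure(rows, class = c("ltr_saturation", class(tibble())))
}
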