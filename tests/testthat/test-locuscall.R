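# Catalog assignment, CPM quantification, novel-locus discovery and
# classification, saturation.

mk_catalog <- function(...) {
  recs <- tibble::tribble(...)
  recs$strand <- "+"; recs$element_type <- "solo_LTR"
  recs$ltr_subtype <- "LTR5_Hs"; recs$catalog_status <- "reference"
  as_catalog(recs)
}

mk_alignments <- function(junctions, contig = "chr1",
                          side = "left_of_flank", ltr_end = "three_prime") {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_along(junctions)),
    ltr_end = ltr_end, flank_seq = strrep("A", 50),
    contig = contig, pos = junctions, strand = "+", score = 50L,
    n_best = 1L, status = "unique", junction = as.integer(junctions),
    junction_side = side)
}

test_that("assignment honours the 10-nt window at the exact boundary", {
  ctl <- mk_catalog(~locus_id, ~contig, ~start, ~end,
                    "L1", "chr1", 1000L, 2000L)
  asg <- assign_to_catalog(mk_alignments(c(2010L, 2011L, 990L, 989L)), ctl,
                           window_nt = 10)
  expect_equal(asg$counts$count, 2L)           # edge+10 and start-10 assigned
  expect_equal(nrow(asg$unassigned), 2L)       # edge+11 and start-11 not
})

test_that("assignment matches a brute-force nearest-window search", {
  set.seed(30)
  n_loci <- 40
  cat_tbl <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:n_loci),
    contig = sample(c("chr1", "chr2"), n_loci, replace = TRUE),
    start = as.integer(sample.int(100000, n_loci)))
  cat_tbl$end <- cat_tbl$start + 968L
  cat_tbl$strand <- "+"; cat_tbl$element_type <- "solo_LTR"
  cat_tbl$ltr_subtype <- "LTR5_Hs"; cat_tbl$catalog_status <- "reference"
  ctl <- as_catalog(cat_tbl)
  juncs <- sample.int(102000, 400)
  ctgs <- sample(c("chr1", "chr2"), 400, replace = TRUE)
  al <- mk_alignments(juncs, contig = ctgs)
  asg <- assign_to_catalog(al, ctl, window_nt = 10)

  # brute force: nearest edge distance, tie -> lower start
  want <- character(400)
  for (i in 1:400) {
    sub <- cat_tbl[cat_tbl$contig == ctgs[i], ]
    d <- pmax(sub$start - juncs[i], juncs[i] - sub$end, 0L)
    if (min(d) <= 10) {
      cand <- sub[d == min(d), ]
      want[i] <- cand$locus_id[which.min(cand$start)]
    } else {
      want[i] <- NA_character_
    }
  }
  got <- rep(NA_character_, 400)
  got[match(asg$assigned$read_id, al$read_id)] <- asg$assigned$locus_id
  expect_identical(got, want)
  # conservation: every unique read lands in exactly one bucket
  expect_equal(nrow(asg$assigned) + nrow(asg$unassigned), 400L)
  expect_equal(sum(asg$counts$count), nrow(asg$assigned))
})

test_that("CPM arithmetic and the >= 50 filter behave at the threshold", {
  counts <- tibble::tibble(locus_id = c("A", "B", "C"),
                           count = c(5L, 4L, 0L))
  q <- quantify(counts, library_size = 100000L, cpm_min = 50)
  expect_equal(q$cpm, c(50, 40, 0))
  expect_equal(q$detected, c(TRUE, TRUE, FALSE))
  expect_equal(q$detected_filtered, c(TRUE, FALSE, FALSE))

  one <- quantify(tibble::tibble(locus_id = "A", count = 7L),
                  library_size = 7L)
  expect_equal(one$cpm, 1e6)

  expect_error(quantify(counts, library_size = 0), "positive")

  # cpm ratio equals count ratio (library size cancels)
  set.seed(31)
  cts <- tibble::tibble(locus_id = sprintf("L%d", 1:20),
                        count = as.integer(sample.int(500, 20)))
  qq <- quantify(cts, library_size = 12345L)
  expect_equal(qq$cpm[1] / qq$cpm[2], cts$count[1] / cts$count[2])
})

test_that("novel discovery applies the 2-kb rule at its boundary", {
  ctl <- mk_catalog(~locus_id, ~contig, ~start, ~end,
                    "L1", "chr1", 10000L, 11000L)
  # cluster of 3 junctions ending 1,999 nt from the locus -> ambiguous
  near <- mk_alignments(c(8001L, 8001L, 8000L))
  # cluster 2,001 nt away -> candidate
  far <- mk_alignments(c(7999L, 7999L, 7998L))
  cl_near <- discover_novel(near, ctl)
  cl_far <- discover_novel(far, ctl)
  expect_equal(cl_near$status, "ambiguous")
  expect_equal(cl_near$dist_to_catalog, 1999)
  expect_equal(cl_far$status, "candidate")
  expect_equal(cl_far$dist_to_catalog, 2001)

  expect_equal(nrow(discover_novel(near[0, ], ctl)), 0L)
  # single-read clusters fall below min_reads = 2
  expect_equal(nrow(discover_novel(mk_alignments(30000L), ctl)), 0L)
})

test_that("TSD classification recovers the printed non-reference footprint", {
  ctl <- mk_catalog(~locus_id, ~contig, ~start, ~end,
                    "L1", "chr6", 100000L, 101000L)
  # clusters around the published N6p21.32 footprint: left-side junctions
  # at 32643458 (0-based) and right-side at 32643464
  al <- dplyr::bind_rows(
    mk_alignments(rep(32643458L, 3), contig = "chr6",
                  side = "left_of_flank", ltr_end = "three_prime"),
    mk_alignments(rep(32643464L, 3), contig = "chr6",
                  side = "right_of_flank", ltr_end = "five_prime"))
  al$read_id <- sprintf("r%04d", seq_len(nrow(al)))
  cand <- discover_novel(al, ctl)
  expect_equal(nrow(cand), 1L)
  cls <- classify_novel(cand)
  expect_equal(cls$classification, "novel_non_reference")
  expect_equal(cls$tsd_start, 32643459L)   # 1-based inclusive
  expect_equal(cls$tsd_end, 32643464L)
  expect_equal(cls$tsd_len, 6L)

  # support from one LTR end only -> ambiguous
  one_side <- mk_alignments(rep(32643458L, 3), contig = "chr6")
  cls1 <- classify_novel(discover_novel(one_side, ctl))
  expect_equal(cls1$classification, "ambiguous")
})

test_that("uncatalogued simulated insertions are rediscovered with their TSD", {
  specs <- sim_insertions(n_loci = 20, n_contigs = 1, contig_len = 3e5,
                          n_repeat = 0, tsd_len = 6, seed = 33)
  # drop two insertions from the catalog: one non-reference, one reference
  specs$in_reference_sequence[3] <- FALSE
  specs$in_catalog[c(3, 10)] <- FALSE
  truth <- build_genome(specs, seed = 33)
  truth$params <- default_protocol(seq_error_rate = 0)
  pairs <- suppressWarnings(simulate_reads(truth, depth = 8000, seed = 33))
  idx <- build_index(truth$reference)
  res <- process_sample(pairs, truth$catalog, idx)
  cand <- discover_novel(res$unassigned, truth$catalog)
  novel <- classify_novel(cand, ltr_annotation = truth$ltr_track)

  info <- truth$insertions
  # the uncatalogued non-reference insertion: recovered with its 6-bp TSD
  nref <- dplyr::filter(novel, .data$classification == "novel_non_reference")
  expect_equal(nrow(nref), 1L)
  expect_equal(nref$tsd_len, 6L)
  expect_equal(nref$tsd_start, info$junction_down_ref[3] + 1L)
  expect_equal(nref$tsd_end, info$junction_up_ref[3])

  # the uncatalogued reference insertion: classified via the LTR track and
  # reported as the annotated element interval containing the junction
  ref <- dplyr::filter(novel, .data$classification == "novel_reference")
  expect_gte(nrow(ref), 1L)
  expect_true(any(ref$start <= info$junction_up_ref[10] &
                    ref$end >= info$junction_up_ref[10]))
})

test_that("nested saturation is monotone with one row per requested depth", {
  s <- small_sim()
  one <- s$pairs[s$pairs$sample_id == "ind01_r1", ]
  idx <- build_index(s$truth$reference)
  depths <- c(0L, 200L, 500L, 1000L, 2000L, 4000L)
  sat <- saturation(one, depths, s$truth$catalog, idx, seed = 5)
  expect_equal(sat$depth, depths)
  expect_equal(sat$detected[1], 0L)
  expect_true(all(diff(sat$detected) >= 0))
  expect_true(all(diff(sat$detected_filtered[-1]) <= diff(sat$detected[-1]) +
                    max(sat$detected)))  # filtered never exceeds unfiltered
  expect_true(all(sat$detected_filtered <= sat$detected))
  # an over-depth request is NA with a warning
  expect_warning(over <- saturation(one, c(100L, nrow(one) + 1L),
                                    s$truth$catalog, idx, seed = 5),
                 "exceeds")
  expect_true(is.na(over$detected[2]))
})
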