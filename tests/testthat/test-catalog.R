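# Catalog loading, category bookkeeping, window queries and merging.

test_that("packaged fixture reproduces the published category structure", {
  cat1063 <- example_catalog()
  cc <- count_by_category(cat1063)
  get <- function(st, ty) cc$n[cc$catalog_status == st & cc$element_type == ty]
  expect_equal(get("reference", "provirus"), 85L)
  expect_equal(get("reference", "solo_LTR"), 946L)
  expect_equal(get("non_reference", "provirus"), 5L)
  expect_equal(get("non_reference", "solo_LTR"), 27L)
  expect_equal(attr(cc, "total"), 1063L)
  expect_equal(sum(cc$n), 1063L)

  nl <- novel_loci()
  nn <- count_by_category(nl)
  expect_equal(nn$n[nn$catalog_status == "novel_reference"], 30L)
  expect_equal(nn$n[nn$catalog_status == "novel_non_reference"], 5L)
  expect_equal(attr(nn, "total"), 35L)

  # polymorphism annotations carried by the fixture
  expect_equal(sum(cat1063$polymorphic_annotation == "polymorphic"), 69L)
  expect_equal(sum(cat1063$polymorphic_annotation == "fixed"), 89L)
  expect_true("solo-LTR330" %in%
                cat1063$locus_id[cat1063$polymorphic_annotation ==
                                   "polymorphic"])
})

test_that("count_by_category of an empty catalog is all zeros", {
  empty <- as_catalog(example_catalog()[0, ])
  cc <- count_by_category(empty)
  expect_equal(nrow(cc), 0L)
  expect_equal(attr(cc, "total"), 0L)
})

test_that("table dialect converts published 1-based coordinates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype\tgene_context",
    "N6p21.32\tChr6: 32643459-32643464\t(+)\tsolo_LTR\tnovel_non_reference\tLTR5_Hs\tL1PA10"
  ), tf)
  cat6 <- load_catalog(tf, "table_s1_tsv")
  expect_equal(nrow(cat6), 1L)
  expect_equal(cat6$contig, "chr6")
  expect_equal(cat6$start, 32643458L)
  expect_equal(cat6$end, 32643464L)
  expect_equal(cat6$strand, "+")
})

test_that("header-only file loads as an empty catalog", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype", tf)
  expect_equal(nrow(load_catalog(tf, "table_s1_tsv")), 0L)
})

test_that("malformed input is rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype",
    "ok1\tChr1: 100-200\t(+)\tsolo_LTR\treference\tLTR5_Hs",
    "bad1\tChr1: nonsense\t(+)\tsolo_LTR\treference\tLTR5_Hs"
  ), tf)
  expect_error(load_catalog(tf, "table_s1_tsv"), "line 3")

  writeLines(c(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype",
    "bad2\tChr1: 100-200\t(+)\tweird_type\treference\tLTR5_Hs"
  ), tf)
  expect_error(load_catalog(tf, "table_s1_tsv"), "provirus, solo_LTR")

  writeLines(c(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype",
    "bad3\tChr1: 300-200\t(+)\tsolo_LTR\treference\tLTR5_Hs"
  ), tf)
  expect_error(load_catalog(tf, "table_s1_tsv"), "start >= end")

  writeLines(c(
    "locus_id\tcoordinate\torientation\ttype\tstatus\tsubtype",
    "dup\tChr1: 100-968\t(+)\tsolo_LTR\treference\tLTR5_Hs",
    "dup\tChr2: 100-968\t(+)\tsolo_LTR\treference\tLTR5_Hs"
  ), tf)
  expect_error(load_catalog(tf, "table_s1_tsv"), "duplicate locus_id")
})

test_that("load -> write -> load round-trips both dialects field-exactly", {
  cat1063 <- example_catalog()
  for (dialect in c("table_s1_tsv", "bed6plus")) {
    tf <- withr::local_tempfile(fileext = ".txt")
    write_catalog(cat1063, tf, dialect)
    back <- load_catalog(tf, dialect)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(cat1063),
                 ignore_attr = TRUE)
  }
})

test_that("query_window honours the exact window boundary", {
  cat1 <- as_catalog(tibble::tibble(
    locus_id = "L1", contig = "chr1", start = 100L, end = 1100L,
    strand = "+", element_type = "solo_LTR", ltr_subtype = "LTR5_Hs",
    catalog_status = "reference"))
  expect_equal(nrow(query_window(cat1, "chr1", 90L, 10L)), 1L)
  expect_equal(nrow(query_window(cat1, "chr1", 89L, 10L)), 0L)
  expect_equal(nrow(query_window(cat1, "chr1", 1109L, 10L)), 1L)
  expect_equal(nrow(query_window(cat1, "chr1", 1110L, 10L)), 0L)
  # window 0 equals plain interval containment
  expect_equal(nrow(query_window(cat1, "chr1", 100L, 0L)), 1L)
  expect_equal(nrow(query_window(cat1, "chr1", 99L, 0L)), 0L)
  # unknown contig: empty result, not an error
  expect_equal(nrow(query_window(cat1, "chrZ", 100L, 10L)), 0L)
})

test_that("query_window equals a brute-force linear interval scan", {
  set.seed(42)
  n <- 50
  recs <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:n),
    contig = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = as.integer(sample.int(50000, n)),
    strand = "+", element_type = "solo_LTR", ltr_subtype = "LTR5_Hs",
    catalog_status = "reference")
  recs$end <- recs$start + as.integer(sample(100:2000, n, replace = TRUE))
  ctl <- as_catalog(recs)
  for (i in 1:1000) {
    ctg <- sample(c("chr1", "chr2"), 1)
    pos <- sample.int(55000, 1)
    w <- sample(0:50, 1)
    got <- sort(query_window(ctl, ctg, pos, w)$locus_id)
    want <- sort(recs$locus_id[recs$contig == ctg &
                                 recs$start - w <= pos &
                                 pos < recs$end + w])
    expect_identical(got, want)
  }
})

test_that("merge_novel merges, reports proximity rejections, and errors on id collisions", {
  cat1063 <- example_catalog()
  merged <- merge_novel(cat1063, tibble::as_tibble(novel_loci()))
  expect_equal(nrow(merged), 1098L)
  expect_equal(nrow(attr(merged, "merge_report")), 0L)

  # empty list: unchanged
  same <- merge_novel(cat1063, tibble::tibble())
  expect_equal(nrow(same), nrow(cat1063))

  # a novel record 5 nt from an existing locus is rejected as known
  near <- tibble::as_tibble(cat1063[1, ]) |>
    dplyr::mutate(locus_id = "near1", start = .data$end + 5L,
                  end = .data$end + 5L + 6L,
                  catalog_status = "novel_non_reference")
  res <- merge_novel(cat1063, near, window_nt = 10L)
  expect_equal(nrow(res), nrow(cat1063))
  expect_equal(attr(res, "merge_report")$locus_id, "near1")
  expect_equal(attr(res, "merge_report")$reason, "duplicate-of-known")
  # cross-check with the window-query oracle
  expect_gt(nrow(query_window(cat1063, near$contig, near$start, 10L)), 0L)

  clash <- tibble::as_tibble(novel_loci())[1, ]
  clash$locus_id <- cat1063$locus_id[1]
  expect_error(merge_novel(cat1063, clash), "collision")
})

test_that("non-reference records wider than a TSD footprint are rejected", {
  bad <- tibble::tibble(
    locus_id = "wide", contig = "chr1", start = 100L, end = 200L,
    strand = "+", element_type = "solo_LTR", ltr_subtype = "LTR5_Hs",
    catalog_status = "non_reference")
  expect_error(as_catalog(bad), "target-site duplication")
})
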