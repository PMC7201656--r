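# Pipeline orchestration and evaluation statistics.

test_that("repeatability counts follow set algebra", {
  mk_quant_sets <- function(sets, universe) {
    purrr::imap_dfr(sets, function(loci, sid) {
      tibble::tibble(sample_id = sid, locus_id = universe,
                     count = as.integer(universe %in% loci),
                     library_size = 1000L,
                     cpm = as.numeric(universe %in% loci) * 1000,
                     detected = universe %in% loci,
                     detected_filtered = universe %in% loci)
    })
  }
  uni <- sprintf("L%03d", 1:100)
  # identical sets: intersection = union = n
  q_same <- mk_quant_sets(list(r1 = uni[1:40], r2 = uni[1:40]), uni)
  rs <- repeatability_summary(q_same)
  expect_equal(rs$n_detected[rs$what == "all_replicates"], 40L)
  expect_equal(rs$n_detected[rs$what == "any_replicate"], 40L)

  # disjoint sets: intersection 0, union a + b
  q_disj <- mk_quant_sets(list(r1 = uni[1:30], r2 = uni[31:75]), uni)
  rd <- repeatability_summary(q_disj)
  expect_equal(rd$n_detected[rd$what == "all_replicates"], 0L)
  expect_equal(rd$n_detected[rd$what == "any_replicate"], 75L)

  # random detection matrices vs brute-force set operations
  set.seed(50)
  for (i in 1:10) {
    sets <- list(r1 = sample(uni, 60), r2 = sample(uni, 50),
                 r3 = sample(uni, 70))
    rr <- repeatability_summary(mk_quant_sets(sets, uni))
    expect_equal(rr$n_detected[rr$what == "all_replicates"],
                 length(Reduce(intersect, sets)))
    expect_equal(rr$n_detected[rr$what == "any_replicate"],
                 length(Reduce(union, sets)))
    expect_equal(rr$n_detected[match(names(sets), rr$what)],
                 unname(lengths(sets)))
    # invariant: intersection <= per-replicate <= union
    expect_true(all(rr$n_detected[rr$what == "all_replicates"] <=
                      lengths(sets)))
    expect_true(all(lengths(sets) <=
                      rr$n_detected[rr$what == "any_replicate"]))
  }
})

test_that("chi-square detection comparison matches the Pearson formula", {
  # identical counts: statistic 0, p = 1
  same <- chisq_detection(c(900, 900, 900), 1098)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # hand-computed Pearson chi-square for the 2 x 3 table
  cts <- c(900, 910, 905); uni <- 1098
  tab <- rbind(cts, uni - cts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - expected)^2 / expected)
  got <- chisq_detection(cts, uni)
  expect_equal(got$statistic, stat_hand)
  expect_equal(got$df, 2)

  # 2 replicates: equals the standard 2x2 chi-square without correction
  two <- chisq_detection(c(850, 902), 1098)
  ref <- suppressWarnings(
    stats::chisq.test(rbind(c(850, 902), c(1098 - 850, 1098 - 902)),
                      correct = FALSE))
  expect_equal(two$statistic, unname(ref$statistic))
  expect_equal(two$p_value, unname(ref$p.value))

  # invariant under replicate reordering
  expect_equal(chisq_detection(c(905, 900, 910), uni)$statistic,
               got$statistic)
  expect_error(chisq_detection(c(10, 20), 0), "> 0")
})

test_that("CPM correlations reproduce the textbook Pearson computation", {
  mk <- function(values) {
    purrr::imap_dfr(values, function(v, sid) {
      tibble::tibble(sample_id = sid,
                     locus_id = sprintf("L%02d", seq_along(v)),
                     count = 1L, library_size = 1000L, cpm = v,
                     detected = v > 0, detected_filtered = v > 0)
    })
  }
  set.seed(51)
  x <- runif(30, 10, 1000)
  m <- cpm_correlation(mk(list(a = x, b = x)))
  expect_equal(unname(m["a", "b"]), 1)
  m2 <- cpm_correlation(mk(list(a = x, b = 2 * x)))
  expect_equal(unname(m2["a", "b"]), 1)
  m3 <- cpm_correlation(mk(list(a = x, b = -x + 1500)))
  expect_equal(unname(m3["a", "b"]), -1)

  # two-pass textbook formula on random tables
  y <- runif(30, 10, 1000)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  m4 <- cpm_correlation(mk(list(a = x, b = y)))
  expect_equal(unname(m4["a", "b"]), r_hand)
  expect_true(isSymmetric(unclass(m4)))
  expect_equal(unname(diag(m4)), c(1, 1))
})

test_that("age-CPM summary bins half-open and reports a rank correlation", {
  ctl <- as_catalog(tibble::tibble(
    locus_id = sprintf("L%d", 1:6), contig = "chr1",
    start = seq(1000L, 6000L, by = 1000L),
    end = seq(1968L, 6968L, by = 1000L), strand = "+",
    element_type = "solo_LTR", ltr_subtype = "LTR5_Hs",
    catalog_status = "reference",
    est_age_mya = c(2, 4.9, 5, 9, 14, 16)))
  q <- tibble::tibble(sample_id = "s1", locus_id = sprintf("L%d", 1:6),
                      count = 1L, library_size = 1000L,
                      cpm = c(900, 800, 500, 400, 100, 50),
                      detected = TRUE, detected_filtered = TRUE)
  out <- age_cpm_summary(q, ctl, breaks = c(0, 5, 10, 15, 20))
  expect_equal(nrow(out), 4L)
  # age 4.9 in [0,5), age 5 in [5,10): half-open boundaries
  expect_equal(out$n_loci, c(2L, 2L, 1L, 1L))
  expect_lt(attr(out, "rho"), 0)

  # all loci the same age: a single bin
  ctl2 <- ctl
  ctl2$est_age_mya <- 3
  one <- age_cpm_summary(q, as_catalog(tibble::as_tibble(ctl2)),
                         breaks = c(0, 5, 10))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_loci, 6L)
})

test_that("the pipeline is deterministic and cpm_min 0 removes the filter", {
  sr <- small_run()
  s <- sr$sim
  run2 <- run_pipeline(s$pairs, s$truth$catalog, sr$index,
                       samples = s$truth$design$samples)
  expect_identical(sr$run$quant, run2$quant)
  expect_identical(sr$run$novel, run2$novel)

  cfg0 <- pipeline_config(cpm_min = 0)
  one <- s$pairs[s$pairs$sample_id == "ind01_r1", ]
  res0 <- process_sample(one, s$truth$catalog, sr$index, cfg0)
  expect_identical(res0$quant$detected_filtered, res0$quant$detected)
})

test_that("run outputs are written with provenance headers", {
  sr <- small_run()
  s <- sr$sim
  outdir <- withr::local_tempdir()
  run <- run_pipeline(s$pairs[s$pairs$sample_id %in%
                                c("ind01_r1", "ind02_r1"), ],
                      s$truth$catalog, sr$index,
                      samples = dplyr::filter(
                        s$truth$design$samples,
                        .data$sample_id %in% c("ind01_r1", "ind02_r1")),
                      outdir = outdir)
  expect_true(file.exists(file.path(outdir, "ind01_r1_quant.tsv")))
  expect_true(file.exists(file.path(outdir, "run_metrics.json")))
  hdr <- readLines(file.path(outdir, "ind01_r1_quant.tsv"), n = 1)
  expect_match(hdr, "^# ltrmapr run \\| seed=")
  # quant TSV reloads to the in-memory table
  back <- readr::read_tsv(file.path(outdir, "ind01_r1_quant.tsv"),
                          comment = "#", show_col_types = FALSE)
  expect_equal(nrow(back),
               sum(run$quant$sample_id == "ind01_r1"))
})

test_that("saturation and correlation autoplots build", {
  s <- small_sim()
  one <- s$pairs[s$pairs$sample_id == "ind01_r1", ]
  idx <- build_index(s$truth$reference)
  sat <- saturation(one, c(500L, 1500L, 4000L), s$truth$catalog, idx,
                    seed = 6)
  expect_s3_class(autoplot(sat), "ggplot")
  sr <- small_run()
  cm <- cpm_correlation(sr$run$quant)
  expect_s3_class(autoplot(cm), "ggplot")
})
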