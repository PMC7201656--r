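# Genome construction, genotype design and read simulation.

test_that("zero insertions leave the reference equal to the background", {
  specs <- sim_insertions(n_loci = 5, n_contigs = 1, contig_len = 1e5,
                          n_repeat = 0, prop_nonreference = 0, seed = 3)
  empty <- specs[0, ]
  attr(empty, "contigs") <- attr(specs, "contigs")
  truth <- build_genome(empty, seed = 3)
  expect_identical(truth$reference, truth$background)
  expect_equal(nrow(truth$catalog), 0L)
  expect_equal(nrow(truth$hap_layout), 0L)
})

test_that("a non-reference solo LTR leaves the reference untouched and is flanked by its TSD", {
  specs <- sim_insertions(n_loci = 2, n_contigs = 1, contig_len = 1e5,
                          n_repeat = 0, prop_nonreference = 0, tsd_len = 6,
                          seed = 5)
  specs$in_reference_sequence <- c(FALSE, TRUE)
  specs$strand <- "+"
  truth <- build_genome(specs, seed = 5)
  # reference lacks the first element entirely
  expect_equal(nchar(truth$reference[["chr1"]]),
               nchar(truth$background[["chr1"]]) +
                 specs$tsd_len[2] + truth$insertions$element_len[2])
  # carrier haplotype: element flanked by two identical 6-mers
  lay <- dplyr::filter(truth$hap_layout,
                       .data$insertion_id == specs$insertion_id[1],
                       .data$hap == 1)
  hap <- truth$haplotypes[["ind01"]][[1]][["chr1"]]
  tsd_left <- substr(hap, lay$e0 - 6 + 1, lay$e0)
  tsd_right <- substr(hap, lay$e1 + 1, lay$e1 + 6)
  expect_equal(tsd_left, tsd_right)
})

test_that("an age-zero insertion carries the exact subtype consensus", {
  specs <- sim_insertions(n_loci = 1, n_contigs = 1, contig_len = 5e4,
                          n_repeat = 0, prop_nonreference = 0, seed = 9)
  specs$age_mya <- 0
  specs$element_type <- "solo_LTR"
  truth <- build_genome(specs, seed = 9)
  expect_identical(truth$element_seqs[[1]]$seq,
                   hml2_elements()$ltr[[specs$ltr_subtype[1]]])
})

test_that("design_experiment produces the replicate design and discordant genotypes", {
  specs <- sim_insertions(n_loci = 20, n_contigs = 1, contig_len = 3e5,
                          seed = 2)
  des <- design_experiment(specs, 3, 3, polymorphic_fraction = 0.25,
                           seed = 2)
  expect_equal(nrow(des$samples), 9L)

  # fixed loci: hom in every individual
  g <- des$genotypes
  fixed_ids <- des$insertions$insertion_id[!des$insertions$polymorphic]
  expect_true(all(g$genotype[g$insertion_id %in% fixed_ids] == "hom"))

  # every polymorphic locus has at least one discordant pair
  poly_ids <- des$insertions$insertion_id[des$insertions$polymorphic]
  expect_equal(length(poly_ids), 5L)
  for (id in poly_ids) {
    gt <- g$genotype[g$insertion_id == id]
    expect_true(any(gt == "absent") && any(gt != "absent"))
  }

  # polymorphic_fraction 0: all individuals identical
  des0 <- design_experiment(specs, 3, 2, polymorphic_fraction = 0, seed = 2)
  wide <- tidyr::pivot_wider(des0$genotypes, names_from = "individual",
                             values_from = "genotype")
  expect_true(all(wide[[2]] == wide[[3]] & wide[[3]] == wide[[4]]))

  expect_error(design_experiment(specs, 1, 2, polymorphic_fraction = 0.5),
               ">= 2 individuals")
})

test_that("chimeric flank substrings occur verbatim at the recorded coordinates (error 0)", {
  s <- small_sim()
  tags <- parse_truth_tags(s$pairs$read_id)
  host <- which(tags$kind == "host")[1:200]
  for (i in host) {
    ins_id <- tags$ins[i]
    junc <- tags$junc[i]
    ctg <- tags$junc_contig[i]
    # the junction-adjacent 20-mers must occur in the reference assembly
    ref <- s$truth$reference[[ctg]]
    info <- s$truth$insertions[
      s$truth$insertions$insertion_id == ins_id, ]
    side_up <- junc == info$junction_up_ref
    if (side_up) {
      flank20 <- substr(ref, junc - 19, junc)
    } else {
      flank20 <- substr(ref, junc + 1, junc + 20)
    }
    # one of the two reads contains the flank (possibly reverse-complemented)
    found <- grepl(flank20, s$pairs$seq1[i], fixed = TRUE) ||
      grepl(flank20, s$pairs$seq2[i], fixed = TRUE) ||
      grepl(oracle_revcomp(flank20), s$pairs$seq1[i], fixed = TRUE) ||
      grepl(oracle_revcomp(flank20), s$pairs$seq2[i], fixed = TRUE)
    expect_true(found)
  }
})

test_that("same seed and parameters reproduce byte-identical reads", {
  s <- small_sim()
  again <- suppressWarnings(simulate_reads(s$truth, depth = 4000, seed = 11))
  expect_identical(s$pairs, again)
  different <- suppressWarnings(simulate_reads(s$truth, depth = 4000,
                                               seed = 12))
  expect_false(identical(s$pairs, different))
})

test_that("an empty genome with zero off-target fraction yields no reads", {
  specs <- sim_insertions(n_loci = 5, n_contigs = 1, contig_len = 1e5,
                          n_repeat = 0, seed = 3)
  empty <- specs[0, ]
  attr(empty, "contigs") <- attr(specs, "contigs")
  truth <- build_genome(empty, seed = 3)
  truth$params <- default_protocol(off_target_fraction = 0)
  reads <- simulate_reads(truth, depth = 100, seed = 1)
  expect_equal(nrow(reads), 0L)
  expect_error(simulate_reads(truth, depth = 0, seed = 1), "> 0")
})

test_that("emitted molecules respect size selection and read length", {
  s <- small_sim()
  expect_true(all(nchar(s$pairs$seq1) <= 150))
  expect_true(all(nchar(s$pairs$seq2) <= 150))
  # reconstruct molecule lengths for fully-overlapping pairs via merging
  one <- s$pairs[s$pairs$sample_id == s$pairs$sample_id[1], ][1:500, ]
  merged <- merge_pairs(one)
  ml <- nchar(merged$seq[merged$merged])
  expect_true(all(ml >= 250 & ml <= 450))
})

test_that("FASTQ output round-trips", {
  s <- small_sim()
  one <- s$pairs[s$pairs$sample_id == s$pairs$sample_id[1], ][1:100, ]
  dir <- withr::local_tempdir()
  paths <- write_fastq_pairs(one, dir)
  back <- read_fastq_pairs(paths$r1[1], paths$r2[1],
                           sample_id = one$sample_id[1])
  expect_equal(back$seq1, one$seq1)
  expect_equal(back$seq2, one$seq2)
  expect_equal(back$read_id, one$read_id)
})

test_that("count-level simulator produces the requested design", {
  qt <- simulate_quant_tables(n_fixed = 50, n_polymorphic = 5,
                              n_individuals = 3, n_replicates = 2,
                              library_size = 1e4, seed = 4)
  expect_equal(nrow(qt$samples), 6L)
  expect_equal(nrow(qt$quant), 6L * 55L)
  pres <- qt$truth$presence
  for (id in qt$truth$loci$locus_id[qt$truth$loci$polymorphic]) {
    p <- pres$present[pres$locus_id == id]
    expect_true(any(p) && any(!p))
  }
  expect_true(all(pres$present[
    pres$locus_id %in% qt$truth$loci$locus_id[!qt$truth$loci$polymorphic]]))
})
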