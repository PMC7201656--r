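# Packaged catalog fixtures.
#
# The published locus compilation itself (a supplementary table) is not
# redistributed; example_catalog() deterministically regenerates a catalog
# with the published category structure (85 reference proviruses, 946
# reference solo LTRs, 5 non-reference proviruses, 27 non-reference solo
# LTRs; 69 loci annotated polymorphic, 89 fixed-in-Chinese) on synthetic
# coordinates. The 35 novel loci (novel_loci()) carry their published
# coordinates.

#' The 35 novel integration loci
#'
#' The 30 novel reference solo-LTR insertions and 5 novel non-reference
#' insertions (catalogued as their target-site-duplication footprint), with
#' published 1-based inclusive coordinates converted to the internal 0-based
#' half-open convention. Flanking-gene annotations ride along as free text.
#'
#' @return A `hervk_catalog` of 35 records.
#' @export
novel_loci <- function() {
  ref <- tibble::tribble(
    ~locus_id, ~coord, ~s1, ~e1, ~strand, ~ltr_subtype, ~gene_context,
    "solo-1p35.1",    "chr1", 33529117L, 33530085L, "+", "LTR5_Hs", NA,
    "solo-3p12.3",    "chr3", 75586870L, 75587898L, "+", "LTR5A",
      "1.3 kb upstream of CTD-2023G6.3",
    "solo-3q21.2",    "chr3", 125518094L, 125519118L, "-", "LTR5A",
      "1.3 kb downstream of LOC105374312",
    "solo-4p16.3",    "chr4", 4076017L, 4077040L, "+", "LTR5A",
      "BC042823 (exon5/5)",
    "solo-4p16.1a",   "chr4", 9036143L, 9037177L, "-", "LTR5A", NA,
    "solo-4p16.1b",   "chr4", 9568938L, 9569963L, "-", "LTR5A",
      "AF073924 (intron 13/41)",
    "solo-6p22.2",    "chr6", 25999459L, 26000425L, "+", "LTR5_Hs",
      "U91328.19 (exon 2/2)",
    "solo-7p14.3",    "chr7", 30758200L, 30759205L, "-", "LTR5B",
      "INMT (intron 1/3)",
    "solo-8p23.1a",   "chr8", 12481601L, 12482613L, "+", "LTR5A",
      "LOC729732 (intron 2/5)",
    "solo-8p23.1b",   "chr8", 6984509L, 6985529L, "-", "LTR5A", NA,
    "solo-8p23.1c",   "chr8", 7957620L, 7958646L, "-", "LTR5A",
      "FAM85B (exon 4/4)",
    "solo-8p12",      "chr8", 29976041L, 29976903L, "-", "LTR5B",
      "LEPROTL1 transcript variant 2 (intron3/3)",
    "solo-10q24.1",   "chr10", 99176602L, 99177875L, "-", "LTR5_Hs",
      "0.6 kb upstream of LOC644215, with Alu int",
    "solo-11q12.2",   "chr11", 60480658L, 60481952L, "-", "LTR5_Hs",
      "MS4A8 (intron5/6), with Alu int",
    "solo-11p15.4a",  "chr11", 3566582L, 3567605L, "+", "LTR5A",
      "LOC101927708 (intron1/2)",
    "solo-11p15.4b",  "chr11", 4481698L, 4482706L, "-", "LTR5B", NA,
    "solo-12q23.3",   "chr12", 108220231L, 108221198L, "-", "LTR5_Hs",
      "KJ893228 (coding PRDM4) (intron 4/13)",
    "solo-16q23.1",   "chr16", 75848903L, 75850194L, "-", "LTR5_Hs",
      "with Alu int",
    "solo-19q13.41",  "chr19", 53435868L, 53437508L, "-", "LTR5B",
      "ZNF321P (intron1/1), with Alu int",
    "solo-19p12",     "chr19", 23459830L, 23461346L, "-", "LTR5B",
      "with LTR6A int",
    "solo-20p11.21a", "chr20", 23736917L, 23737884L, "-", "LTR5_Hs", NA,
    "solo-20p11.21b", "chr20", 23674997L, 23675964L, "-", "LTR5_Hs", NA,
    "solo-Yq11.223",  "chrY", 26026513L, 26027237L, "-", "LTR5_Hs", NA,
    "solo-Yq11.23",   "chrY", 27935164L, 27935888L, "+", "LTR5_Hs", NA,
    "solo-Un212", "Un_gl000212", 79707L, 80671L, "+", "LTR5_Hs", NA,
    "solo-Un219", "Un_gl000219", 31165L, 32127L, "-", "LTR5_Hs", NA,
    "solo-Un222", "Un_gl000222", 107341L, 108304L, "-", "LTR5_Hs", NA,
    "solo-Un231", "Un_gl000231", 22479L, 23506L, "+", "LTR5A", NA,
    "solo-Un232a", "Un_gl000232", 2327L, 3289L, "+", "LTR5_Hs", NA,
    "solo-Un232b", "Un_gl000232", 8571L, 9521L, "-", "LTR5_Hs", NA
  ) |>
    mutate(catalog_status = "novel_reference")
  nonref <- tibble::tribble(
    ~locus_id, ~coord, ~s1, ~e1, ~strand, ~ltr_subtype, ~gene_context,
    "N3q22.1",   "chr3", 130166557L, 130166563L, "+", "unknown",
      "HERVK11-int, COL6A5 (intron 36/41)",
    "N6p21.32",  "chr6", 32643459L, 32643464L, "+", "LTR5_Hs", "L1PA10",
    "N15q21.2",  "chr15", 51650823L, 51650829L, "+", "unknown",
      "HERV17-int, GLDN (intron 1/9)",
    "N19q11",    "chr19", 28198583L, 28198588L, "+", "unknown",
      "inserted into HERV17-int",
    "N21q22.11", "chr21", 33824215L, 33824220L, "-", "unknown",
      "MLT1C, EVA1c (intron 1/7)"
  ) |>
    mutate(catalog_status = "novel_non_reference")
  recs <- bind_rows(ref, nonref) |>
    mutate(contig = .data$coord,
           start = .data$s1 - 1L,  # published 1-based inclusive
           end = .data$e1,
           element_type = "solo_LTR",
           polymorphic_annotation = "unknown") |>
    select(-"coord", -"s1", -"e1")
  as_catalog(recs, source = "novel loci table")
}

#' Deterministic 1063-locus example catalog
#'
#' Regenerates a catalog with the published category counts — 85 reference
#' provirus, 946 reference solo-LTR, 5 non-reference provirus and 27
#' non-reference solo-LTR records (1063 in total) — on synthetic
#' coordinates spread over chr1-chr22, chrX and chrY. 69 records (all 32
#' non-reference loci, including the named solo-LTR330, plus 37 reference
#' solo LTRs) carry a `polymorphic` annotation and a population frequency;
#' a further 89 reference loci are annotated `fixed` with frequency 1.
#' Subtypes and estimated ages are drawn per record (LTR5_Hs youngest
#' through LTR5B oldest). The same seed always returns the same catalog.
#'
#' @param seed Integer seed fixing the synthetic coordinates/annotations.
#' @return A `hervk_catalog` of 1063 records.
#' @export
example_catalog <- function(seed = 20200506L) {
  with_seed(seed, {
    n_rp <- 85L; n_rs <- 946L; n_np <- 5L; n_ns <- 27L
    n <- n_rp + n_rs + n_np + n_ns
    ids <- c(sprintf("provirus%03d", seq_len(n_rp)),
             sprintf("solo-LTR%d", seq_len(n_rs)),
             sprintf("nonref-prov%d", seq_len(n_np)),
             sprintf("nonref-solo%d", seq_len(n_ns)))
    etype <- rep(c("provirus", "solo_LTR", "provirus", "solo_LTR"),
                 c(n_rp, n_rs, n_np, n_ns))
    status <- rep(c("reference", "reference", "non_reference",
                    "non_reference"), c(n_rp, n_rs, n_np, n_ns))
    chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
    contig <- chroms[(seq_len(n) - 1L) %% length(chroms) + 1L]
    slot <- integer(n)
    for (cg in chroms) {
      idx <- which(contig == cg)
      slot[idx] <- seq_along(idx)
    }
    start <- 1000000L + (slot - 1L) * 25000L
    len <- if_else(status %in% c("non_reference"), 6L,
                   if_else(etype == "provirus", 9470L, 968L))
    subtype <- sample(c("LTR5_Hs", "LTR5A", "LTR5B"), n, replace = TRUE,
                      prob = c(0.45, 0.3, 0.25))
    age_lo <- c(LTR5_Hs = 0.5, LTR5A = 6, LTR5B = 10)[subtype]
    age_hi <- c(LTR5_Hs = 6, LTR5A = 12, LTR5B = 18)[subtype]
    age <- round(runif(n, age_lo, age_hi), 2)

    poly <- rep(FALSE, n)
    poly[status == "non_reference"] <- TRUE               # 32 loci
    ref_solo <- which(status == "reference" & etype == "solo_LTR")
    poly[ref_solo[c(330L, sample(setdiff(seq_along(ref_solo), 330L), 36L))]] <-
      TRUE                                                # + 37 = 69 total
    fixed <- rep(FALSE, n)
    fixed[sample(which(!poly), 89L)] <- TRUE              # fixed in Chinese
    annot <- if_else(poly, "polymorphic", if_else(fixed, "fixed", "unknown"))
    freq <- dplyr::case_when(poly ~ round(runif(n, 0.05, 0.95), 2),
                             fixed ~ 1,
                             TRUE ~ NA_real_)
    recs <- tibble(
      locus_id = ids, contig = contig, start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      element_type = etype, ltr_subtype = subtype, catalog_status = status,
      polymorphic_annotation = annot, population_frequency = freq,
      est_age_mya = age, gene_context = NA_character_)
    as_catalog(recs, source = "example_catalog()")
  })
}
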