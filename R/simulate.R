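# Protocol simulator: synthetic genomes, genotypes and LTR-targeted
# enrichment reads with full ground truth.
#
# The wet-lab phase being emulated: genomic DNA is randomly fragmented, a
# linker is ligated to fragment ends, suppression + nested PCR selects
# fragments carrying an LTR terminus (primer mismatches down-weight
# amplification), 250-450 bp molecules are size-selected and sequenced
# PE150. Each on-target molecule is therefore
#   [primer_offset terminal LTR bases][host or internal flank][linker]
# written in primer orientation; off-target molecules are plain genomic
# fragments that escaped suppression.

#' Draw a set of insertion specifications
#'
#' Places `n_loci` HML-2 insertions on a synthetic multi-contig genome:
#' proviruses and solo LTRs across the three LTR subtypes, with ages drawn
#' per subtype (LTR5_Hs youngest, LTR5B oldest), a fixed-length target-site
#' duplication, a configurable share of non-reference insertions (absent
#' from the reference assembly, catalogued as their TSD footprint) and of
#' repeat-embedded insertions (whose flank context is duplicated elsewhere
#' in the genome so their flanks cannot map uniquely).
#'
#' @param n_loci Total insertions.
#' @param n_contigs,contig_len Genome shape.
#' @param prop_provirus Share of proviral (two-LTR) insertions.
#' @param prop_nonreference Share of non-reference insertions.
#' @param n_repeat Number of repeat-embedded insertions.
#' @param tsd_len Target-site duplication length (bp).
#' @param subtype_props Named sampling weights for LTR subtypes.
#' @param allele_frequency Carrier allele frequency used for loci later
#'   designated polymorphic.
#' @param seed Integer seed.
#' @return Tibble of insertion specs with attribute `"contigs"` (named
#'   contig lengths).
#' @export
sim_insertions <- function(n_loci = 120L, n_contigs = 3L,
                           contig_len = 400000L,
                           prop_provirus = 0.2,
                           prop_nonreference = 0.08,
                           n_repeat = 4L,
                           tsd_len = 6L,
                           subtype_props = c(LTR5_Hs = 0.45, LTR5A = 0.30,
                                             LTR5B = 0.25),
                           allele_frequency = 0.5,
                           seed = 1L) {
  stopifnot(n_loci >= 1, n_contigs >= 1, tsd_len >= 1, tsd_len <= 20)
  contigs <- setNames(rep(as.integer(contig_len), n_contigs),
                      paste0("chr", seq_len(n_contigs)))
  with_seed(seed, {
    per <- diff(floor(seq(0, n_loci, length.out = n_contigs + 1)))
    margin <- 5000L
    rows <- purrr::map2_dfr(names(contigs), per, function(ctg, k) {
      if (k == 0) return(tibble())
      span <- contigs[[ctg]] - 2L * margin
      slot <- span / k
      if (slot < 6000) abort("contigs too short for the requested locus count")
      base <- margin + floor((seq_len(k) - 1) * slot)
      jitter <- floor(runif(k, 0, pmax(1, slot - 6000)))
      tibble(contig = ctg, site = as.integer(base + jitter))
    })
    n <- nrow(rows)
    subtype <- sample(names(subtype_props), n, replace = TRUE,
                      prob = subtype_props)
    age_rng <- list(LTR5_Hs = c(0.5, 6), LTR5A = c(6, 12), LTR5B = c(10, 18))
    age <- vapply(subtype, function(s) runif(1, age_rng[[s]][1],
                                             age_rng[[s]][2]), numeric(1))
    etype <- if_else(runif(n) < prop_provirus, "provirus", "solo_LTR")
    nonref <- seq_len(n) %in% sample.int(n, round(prop_nonreference * n))
    rep_pool <- which(!nonref)
    in_rep <- seq_len(n) %in% sample(rep_pool, min(n_repeat, length(rep_pool)))
    specs <- rows |>
      mutate(insertion_id = sprintf("ins%03d", seq_len(n)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             element_type = etype,
             ltr_subtype = subtype,
             age_mya = round(age, 2),
             tsd_len = as.integer(tsd_len),
             in_reference_sequence = !nonref,
             in_repeat = in_rep,
             allele_frequency = allele_frequency,
             in_catalog = TRUE) |>
      relocate("insertion_id")
    attr(specs, "contigs") <- contigs
    specs
  })
}

#' Assign genotypes and a replicate design
#'
#' Designates a fraction of the insertions as polymorphic and draws diploid
#' presence/absence genotypes per individual (replicates share genotypes).
#' Fixed loci are homozygous-present in every individual. Every polymorphic
#' locus is guaranteed at least one discordant individual pair (one carrier
#' and one non-carrier). Repeat-embedded loci are kept fixed so that their
#' loss is attributable to the unique-mapping filter alone.
#'
#' @param insertions Tibble from [sim_insertions()].
#' @param n_individuals,n_replicates Experimental design.
#' @param polymorphic_fraction Fraction of loci made polymorphic.
#' @param seed Integer seed.
#' @return List with `insertions` (a `polymorphic` column added),
#'   `genotypes` (individual x insertion, `absent`/`het`/`hom`) and
#'   `samples` (sample sheet: `sample_id`, `individual`, `replicate`).
#' @export
design_experiment <- function(insertions, n_individuals = 3L,
                              n_replicates = 3L,
                              polymorphic_fraction = 0.1,
                              seed = 1L) {
  if (polymorphic_fraction < 0 || polymorphic_fraction > 1)
    abort("polymorphic_fraction must be in [0, 1]")
  if (n_individuals < 2 && polymorphic_fraction > 0)
    abort("polymorphic loci need >= 2 individuals for a contrast")
  with_seed(seed, {
    n <- nrow(insertions)
    pool <- which(!insertions$in_repeat)
    n_poly <- min(round(polymorphic_fraction * n), length(pool))
    poly_idx <- sort(sample(pool, n_poly))
    insertions$polymorphic <- seq_len(n) %in% poly_idx

    individuals <- sprintf("ind%02d", seq_len(n_individuals))
    geno <- tidyr::expand_grid(individual = individuals,
                               insertion_id = insertions$insertion_id) |>
      left_join(select(insertions, "insertion_id", "polymorphic",
                       "allele_frequency"),
                by = "insertion_id")
    draw_poly <- function(af, k) {
      for (i in seq_len(100)) {
        ac <- rbinom(k, 2, af)
        if (any(ac > 0) && any(ac == 0)) return(ac)
      }
      c(2L, rep(0L, k - 1L))  # force a discordant pair
    }
    geno <- geno |>
      group_by(.data$insertion_id) |>
      mutate(allele_count = if (first(.data$polymorphic))
               draw_poly(first(.data$allele_frequency), n()) else 2L) |>
      ungroup() |>
      mutate(genotype = c("absent", "het", "hom")[.data$allele_count + 1L]) |>
      select("individual", "insertion_id", "genotype")

    samples <- tidyr::expand_grid(individual = individuals,
                                  replicate = seq_len(n_replicates)) |>
      mutate(sample_id = sprintf("%s_r%d", .data$individual,
                                 .data$replicate)) |>
      relocate("sample_id")
    list(insertions = insertions, genotypes = geno, samples = samples)
  })
}

# Primer-site regions of a realized LTR: the nested primer anneals at
# [bait, offset) from the terminus. Returns mismatch counts vs the
# ancestral-consensus primer for the start- and end-facing sites.
primer_mismatches <- function(ltr_seq, ancestral, bait_len, primer_offset) {
  n <- nchar(ancestral)
  p_start <- substr(ancestral, bait_len + 1L, primer_offset)
  p_end <- substr(ancestral, n - primer_offset + 1L, n - bait_len)
  ln <- nchar(ltr_seq)
  c(start = mismatch_count(substr(ltr_seq, bait_len + 1L, primer_offset),
                           p_start),
    end = mismatch_count(substr(ltr_seq, ln - primer_offset + 1L,
                                ln - bait_len), p_end))
}

#' Build synthetic genomes and the truth manifest
#'
#' Constructs the background genome, the reference assembly (background plus
#' all reference-flagged insertions), and per-individual diploid haplotypes
#' according to the genotype table. Each present insertion places its
#' element plus a `tsd_len`-bp duplication of the site sequence; element
#' LTRs carry locus-specific point mutations at
#' `ltr_mutation_rate_per_mya x age`. Repeat-embedded insertions get their
#' 4-kb flank context copied to two additional genomic locations, so their
#' junction flanks cannot map uniquely.
#'
#' @param insertions Tibble from [sim_insertions()].
#' @param design Optional list from [design_experiment()]; by default a
#'   single individual homozygous for every insertion.
#' @param elements Sequence set from [hml2_elements()].
#' @param params Protocol parameters from [default_protocol()].
#' @param bait_len Bait length used to locate the primer site on the LTR.
#' @param seed Integer seed.
#' @return An `ltr_truth` list: contigs, `reference` assembly, per-individual
#'   haplotype sequences, `hap_layout` (realized element intervals per
#'   haplotype), realized `insertions` (reference-space junctions, element
#'   lengths, per-end primer mismatches), the simulation `catalog`
#'   (`in_catalog` records only), `catalog_full` (novel insertions included,
#'   with `novel_*` statuses), `ltr_track` (LTR intervals in reference
#'   coordinates) and the design.
#' @export
build_genome <- function(insertions, design = NULL,
                         elements = hml2_elements(),
                         params = default_protocol(),
                         bait_len = 20L, seed = 1L) {
  contigs <- attr(insertions, "contigs")
  if (is.null(contigs)) abort("insertions must carry a 'contigs' attribute")
  if (is.null(design)) {
    if (!"polymorphic" %in% names(insertions))
      insertions$polymorphic <- FALSE
    design <- list(
      insertions = insertions,
      genotypes = tibble(individual = "ind01",
                         insertion_id = insertions$insertion_id,
                         genotype = "hom"),
      samples = tibble(sample_id = "ind01_r1", individual = "ind01",
                       replicate = 1L))
  }
  ins <- design$insertions
  ins <- arrange(ins, .data$contig, .data$site)

  # --- validation -----------------------------------------------------------
  if (any(ins$site < 0 | ins$site > contigs[ins$contig]))
    abort("insertion site outside contig")
  gaps <- ins |> group_by(.data$contig) |>
    summarise(min_gap = if (n() > 1) min(diff(.data$site)) else Inf)
  if (any(gaps$min_gap < 1000))
    abort("insertion sites must be >= 1 kb apart")
  if (any(ins$tsd_len > 20)) abort("tsd_len must be <= 20")

  with_seed(seed, {
    background <- setNames(random_dna(unname(contigs)), names(contigs))

    # --- repeat cassettes: copy flank context of repeat-embedded loci -------
    half <- 2000L
    for (i in which(ins$in_repeat)) {
      ctg <- ins$contig[i]; s <- ins$site[i]
      cassette <- substr(background[[ctg]], s - half + 1L, s + half)
      for (cp in 1:2) {
        ok <- FALSE
        for (try in 1:50) {
          tc <- sample(names(contigs), 1)
          tp <- floor(runif(1, 6000, contigs[[tc]] - 6000 - 2 * half))
          # keep the copy clear of every insertion's fragment span
          near <- ins$contig == tc & ins$site > tp - 600 &
            ins$site < tp + 2 * half + 600
          if (!any(near)) { ok <- TRUE; break }
        }
        if (!ok) abort("could not place repeat cassette copy")
        substr(background[[tc]], tp + 1L, tp + 2L * half) <- cassette
      }
    }

    # --- realized element sequences ----------------------------------------
    rate <- params$ltr_mutation_rate_per_mya
    elem <- purrr::map(seq_len(nrow(ins)), function(i) {
      sub <- ins$ltr_subtype[i]
      r <- rate * ins$age_mya[i]
      if (ins$element_type[i] == "provirus") {
        l5 <- mutate_seq(elements$ltr[[sub]], r)
        l3 <- mutate_seq(elements$ltr[[sub]], r)
        int <- mutate_seq(elements$internal, r)
        list(ltr5 = l5, ltr3 = l3, internal = int,
             seq = paste0(l5, int, l3))
      } else {
        l <- mutate_seq(elements$ltr[[sub]], r)
        list(ltr5 = l, ltr3 = l, internal = "", seq = l)
      }
    })
    names(elem) <- ins$insertion_id
    ins$element_len <- vapply(elem, function(e) nchar(e$seq), numeric(1)) |>
      as.integer()
    ins$ltr5_len <- vapply(elem, function(e) nchar(e$ltr5), numeric(1)) |>
      as.integer()
    ins$ltr3_len <- vapply(elem, function(e) nchar(e$ltr3), numeric(1)) |>
      as.integer()

    # primer mismatches: outer/inner sites per LTR copy
    pm <- purrr::map_dfr(seq_len(nrow(ins)), function(i) {
      m5 <- primer_mismatches(elem[[i]]$ltr5, elements$ancestral, bait_len,
                              params$primer_offset)
      m3 <- primer_mismatches(elem[[i]]$ltr3, elements$ancestral, bait_len,
                              params$primer_offset)
      tibble(m5_start = m5[["start"]], m5_end = m5[["end"]],
             m3_start = m3[["start"]], m3_end = m3[["end"]])
    })
    ins <- bind_cols(ins, pm)

    # --- reference assembly + reference-space junctions ---------------------
    reference <- background
    ins$junction_up_ref <- NA_integer_
    ins$junction_down_ref <- NA_integer_
    ltr_track <- list()
    for (ctg in names(contigs)) {
      idx <- which(ins$contig == ctg)
      if (length(idx) == 0) next
      pieces <- character(); prev <- 0L; off <- 0L
      g <- background[[ctg]]
      for (i in idx) {
        s <- ins$site[i]; d <- ins$tsd_len[i]
        if (ins$in_reference_sequence[i]) {
          a <- s + d + off
          b <- a + ins$element_len[i]
          ins$junction_up_ref[i] <- a
          ins$junction_down_ref[i] <- b
          eseq <- elem[[i]]$seq
          if (ins$strand[i] == "-") eseq <- revcomp(eseq)
          pieces <- c(pieces, substr(g, prev + 1L, s + d), eseq)
          prev <- s
          off <- off + d + ins$element_len[i]
          if (ins$element_type[i] == "provirus") {
            if (ins$strand[i] == "+") {
              ltr_track <- c(ltr_track,
                             list(tibble(contig = ctg, start = a,
                                         end = a + ins$ltr5_len[i]),
                                  tibble(contig = ctg,
                                         start = b - ins$ltr3_len[i],
                                         end = b)))
            } else {
              ltr_track <- c(ltr_track,
                             list(tibble(contig = ctg, start = a,
                                         end = a + ins$ltr3_len[i]),
                                  tibble(contig = ctg,
                                         start = b - ins$ltr5_len[i],
                                         end = b)))
            }
          } else {
            ltr_track <- c(ltr_track,
                           list(tibble(contig = ctg, start = a, end = b)))
          }
        } else {
          ins$junction_down_ref[i] <- s + off
          ins$junction_up_ref[i] <- s + d + off
        }
      }
      pieces <- c(pieces, substr(g, prev + 1L, nchar(g)))
      reference[[ctg]] <- paste(pieces, collapse = "")
    }
    ltr_track <- bind_rows(ltr_track)

    # --- per-individual haplotypes -----------------------------------------
    individuals <- unique(design$genotypes$individual)
    haplotypes <- list()
    hap_layout <- list()
    for (ind in individuals) {
      g_ind <- filter(design$genotypes, .data$individual == ind)
      for (h in 1:2) {
        present <- ins$insertion_id %in%
          g_ind$insertion_id[g_ind$genotype == "hom" |
                               (g_ind$genotype == "het" & h == 1L)]
        hap <- background
        for (ctg in names(contigs)) {
          idx <- which(ins$contig == ctg & present)
          if (length(idx) == 0) next
          pieces <- character(); prev <- 0L; off <- 0L
          g <- background[[ctg]]
          for (i in idx) {
            s <- ins$site[i]; d <- ins$tsd_len[i]
            e0 <- s + d + off
            eseq <- elem[[i]]$seq
            if (ins$strand[i] == "-") eseq <- revcomp(eseq)
            pieces <- c(pieces, substr(g, prev + 1L, s + d), eseq)
            prev <- s
            off <- off + d + ins$element_len[i]
            hap_layout <- c(hap_layout, list(tibble(
              individual = ind, hap = h,
              insertion_id = ins$insertion_id[i],
              contig = ctg, e0 = e0, e1 = e0 + ins$element_len[i])))
          }
          pieces <- c(pieces, substr(g, prev + 1L, nchar(g)))
          hap[[ctg]] <- paste(pieces, collapse = "")
        }
        haplotypes[[ind]][[h]] <- hap
      }
    }
    hap_layout <- bind_rows(hap_layout)
    if (nrow(hap_layout) == 0) {
      hap_layout <- tibble(individual = character(), hap = integer(),
                           insertion_id = character(), contig = character(),
                           e0 = integer(), e1 = integer())
    }

    # --- catalogs ------------------------------------------------------------
    cat_records <- ins |>
      mutate(
        status_true = dplyr::case_when(
          .data$in_catalog & .data$in_reference_sequence ~ "reference",
          .data$in_catalog ~ "non_reference",
          .data$in_reference_sequence ~ "novel_reference",
          TRUE ~ "novel_non_reference"),
        start = if_else(.data$in_reference_sequence,
                        .data$junction_up_ref, .data$junction_down_ref),
        end = if_else(.data$in_reference_sequence,
                      .data$junction_down_ref, .data$junction_up_ref),
        locus_id = .data$insertion_id,
        catalog_status = .data$status_true,
        polymorphic_annotation = if_else(.data$polymorphic, "polymorphic",
                                         "fixed"),
        population_frequency = if_else(.data$polymorphic,
                                       .data$allele_frequency, 1),
        est_age_mya = .data$age_mya,
        gene_context = NA_character_)
    catalog_full <- as_catalog(cat_records, source = "simulated")
    catalog <- as_catalog(filter(cat_records, .data$in_catalog),
                          source = "simulated")

    structure(list(contigs = contigs, background = background,
                   reference = reference, haplotypes = haplotypes,
                   hap_layout = hap_layout, insertions = ins,
                   element_seqs = elem, catalog = catalog,
                   catalog_full = catalog_full, ltr_track = ltr_track,
                   elements = elements, params = params,
                   bait_len = as.integer(bait_len),
                   design = design, seed = seed),
              class = "ltr_truth")
  })
}

#' @export
print.ltr_truth <- function(x, ...) {
  cat(sprintf(
    "# ltr_truth: %d contigs, %d insertions (%d catalogued), %d individuals\n",
    length(x$contigs), nrow(x$insertions), nrow(x$catalog),
    length(x$haplotypes)))
  invisible(x)
}

# Enumerate amplifiable targets for one individual: one row per
# (haplotype-resident insertion, LTR end), host junctions and, for
# proviruses, retrovirus-internal junctions.
enumerate_targets <- function(truth, individual) {
  layout <- filter(truth$hap_layout, .data$individual == .env$individual)
  if (nrow(layout) == 0) return(tibble())
  info <- truth$insertions
  rows <- purrr::map_dfr(seq_len(nrow(layout)), function(r) {
    i <- match(layout$insertion_id[r], info$insertion_id)
    st <- info$strand[i]
    e0 <- layout$e0[r]; e1 <- layout$e1[r]
    l5 <- info$ltr5_len[i]; l3 <- info$ltr3_len[i]
    up_end <- if (st == "+") "five_prime" else "three_prime"
    dn_end <- if (st == "+") "three_prime" else "five_prime"
    up_m <- if (st == "+") info$m5_start[i] else info$m3_end[i]
    dn_m <- if (st == "+") info$m3_end[i] else info$m5_start[i]
    out <- tibble(
      insertion_id = info$insertion_id[i],
      contig = layout$contig[r], hap = layout$hap[r],
      target = c("up_host", "down_host"),
      kind = "host",
      j_hap = c(e0, e1), dir = c(-1L, 1L),
      ltr_end = c(up_end, dn_end),
      m = c(up_m, dn_m),
      j_ref = c(info$junction_up_ref[i], info$junction_down_ref[i]))
    if (info$element_type[i] == "provirus") {
      if (st == "+") {
        internal <- tibble(
          insertion_id = info$insertion_id[i],
          contig = layout$contig[r], hap = layout$hap[r],
          target = c("gag_internal", "env_internal"),
          kind = "internal",
          j_hap = c(e0 + l5, e1 - l3), dir = c(1L, -1L),
          ltr_end = c("three_prime", "five_prime"),
          m = c(info$m5_end[i], info$m3_start[i]),
          j_ref = NA_integer_)
      } else {
        internal <- tibble(
          insertion_id = info$insertion_id[i],
          contig = layout$contig[r], hap = layout$hap[r],
          target = c("gag_internal", "env_internal"),
          kind = "internal",
          j_hap = c(e1 - l5, e0 + l3), dir = c(-1L, 1L),
          ltr_end = c("three_prime", "five_prime"),
          m = c(info$m5_end[i], info$m3_start[i]),
          j_ref = NA_integer_)
      }
      out <- bind_rows(out, internal)
    }
    out
  })
  rows
}

sample_fragment_lengths <- function(n, params) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- round(rnorm(2L * (n - length(out)) + 10L,
                        params$fragment_len_mean, params$fragment_len_sd))
    cand <- cand[cand >= params$size_select_min &
                   cand <= params$size_select_max]
    out <- c(out, as.integer(cand))
  }
  out[seq_len(n)]
}

apply_seq_error <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end enrichment reads
#'
#' Emits PE150-style read pairs per sample. Library molecules contain an LTR
#' terminus with its primer site (primer mismatches reduce amplification
#' via a logistic weight), carry the linker at the genomic end, and pass
#' 250-450 bp size selection; a configurable fraction are off-target
#' background fragments and a fraction `pcr_duplicate_rate` of emitted
#' pairs are PCR duplicates. Read names carry truth tags after the
#' reserved `"::"` separator (molecule id, insertion id, LTR end, molecule
#' kind, reference-space junction), parseable with [parse_truth_tags()].
#'
#' @param truth An `ltr_truth` from [build_genome()].
#' @param depth Read pairs per sample: single value or named vector keyed by
#'   `sample_id`; defaults to `params$depth_reads`.
#' @param params Protocol parameters (defaults to those in `truth`).
#' @param samples Sample sheet (defaults to the design in `truth`).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
simulate_reads <- function(truth, depth = NULL, params = truth$params,
                           samples = truth$design$samples, seed = 1L) {
  depth <- depth %||% params$depth_reads
  if (is.null(names(depth))) {
    depth <- setNames(rep(depth[[1]], nrow(samples)), samples$sample_id)
  }
  if (any(depth[samples$sample_id] <= 0) || anyNA(depth[samples$sample_id]))
    abort("requested depth must be > 0 for every sample")
  linker <- params$linker_seq
  lk <- nchar(linker)
  ltr_in <- params$primer_offset
  rl <- params$read_len
  qconst <- strrep("F", rl)  # flat Q37

  out <- purrr::map_dfr(seq_len(nrow(samples)), function(si) {
    sample_id <- samples$sample_id[si]
    individual <- samples$individual[si]
    with_seed(child_seed(seed, si), {
      D <- as.integer(depth[[sample_id]])
      n_unique <- max(1L, D - as.integer(round(D * params$pcr_duplicate_rate)))
      n_off <- as.integer(round(n_unique * params$off_target_fraction))
      n_on <- n_unique - n_off

      targets <- enumerate_targets(truth, individual)
      mols <- list()
      if (n_on > 0 && nrow(targets) > 0) {
        w <- amp_weight(targets$m, params$amp_k, params$amp_m0)
        counts <- as.vector(rmultinom(1, n_on, w))
        silent <- targets |>
          mutate(count = counts) |>
          filter(.data$kind == "host") |>
          group_by(.data$insertion_id) |>
          summarise(total = sum(.data$count))
        if (any(silent$total == 0)) {
          warn(paste0("no amplifiable molecule emitted for insertion(s): ",
                      paste(silent$insertion_id[silent$total == 0],
                            collapse = ", ")))
        }
        idx <- rep(seq_len(nrow(targets)), counts)
        ltot <- sample_fragment_lengths(length(idx), params)
        flank_len <- ltot - ltr_in - lk
        hapseq <- vapply(seq_along(idx), function(q) {
          t <- targets[idx[q], ]
          truth$haplotypes[[individual]][[t$hap]][[t$contig]]
        }, character(1))
        j <- targets$j_hap[idx]
        dirs <- targets$dir[idx]
        core <- character(length(idx))
        fwd <- dirs == 1L
        core[fwd] <- substring(hapseq[fwd], j[fwd] - ltr_in + 1L,
                               j[fwd] + flank_len[fwd])
        core[!fwd] <- revcomp(substring(hapseq[!fwd],
                                        j[!fwd] - flank_len[!fwd] + 1L,
                                        j[!fwd] + ltr_in))
        mols$on <- tibble(
          m_seq = paste0(core, linker),
          ins = targets$insertion_id[idx],
          end = targets$ltr_end[idx],
          kind = targets$kind[idx],
          junc_contig = targets$contig[idx],
          junc = targets$j_ref[idx])
      }
      if (n_off > 0) {
        ctg <- sample(names(truth$contigs), n_off, replace = TRUE,
                      prob = truth$contigs)
        ltot <- sample_fragment_lengths(n_off, params)
        flen <- ltot - lk
        pos <- floor(runif(n_off) * (truth$contigs[ctg] - flen))
        hap <- vapply(ctg, function(cg)
          truth$haplotypes[[individual]][[1L]][[cg]], character(1))
        frag <- substring(hap, pos + 1L, pos + flen)
        neg <- runif(n_off) < 0.5
        frag[neg] <- revcomp(frag[neg])
        mols$off <- tibble(m_seq = paste0(frag, linker),
                           ins = "bg", end = "na", kind = "background",
                           junc_contig = ".", junc = NA_integer_)
      }
      mol <- bind_rows(mols)
      if (nrow(mol) == 0) {
        return(tibble(sample_id = character(), read_id = character(),
                      seq1 = character(), qual1 = character(),
                      seq2 = character(), qual2 = character()))
      }
      mol$mol_id <- sprintf("m%06d", seq_len(nrow(mol)))
      # mate order is fixed per molecule, so PCR duplicates of a molecule
      # emit identical pairs and collapse under sequence-level dedup
      mol$swap <- runif(nrow(mol)) < 0.5
      # PCR duplicates: re-emit sampled molecules up to depth D
      n_dup <- D - nrow(mol)
      emit <- c(seq_len(nrow(mol)),
                if (n_dup > 0) sample.int(nrow(mol), n_dup, replace = TRUE))
      mol <- mol[emit, ]
      L <- nchar(mol$m_seq)
      r1 <- substring(mol$m_seq, 1L, pmin(rl, L))
      r2 <- revcomp(substring(mol$m_seq, pmax(1L, L - rl + 1L), L))
      swap <- mol$swap
      tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
      r1 <- apply_seq_error(r1, params$seq_error_rate)
      r2 <- apply_seq_error(r2, params$seq_error_rate)
      tibble(
        sample_id = sample_id,
        read_id = sprintf("%s:r%07d::mol=%s;ins=%s;end=%s;kind=%s;junc=%s:%s",
                          sample_id, seq_along(emit), mol$mol_id, mol$ins,
                          mol$end, mol$kind, mol$junc_contig,
                          if_else(is.na(mol$junc), "-1",
                                  as.character(mol$junc))),
        seq1 = r1, qual1 = substring(qconst, 1L, nchar(r1)),
        seq2 = r2, qual2 = substring(qconst, 1L, nchar(r2)))
    })
  })
  out
}

#' Parse truth tags from simulated read names
#'
#' @param read_id Character vector of read names produced by
#'   [simulate_reads()] (tags follow the reserved `"::"` separator).
#' @return Tibble with `read_id`, `mol`, `ins`, `end`, `kind`,
#'   `junc_contig`, `junc`.
#' @export
parse_truth_tags <- function(read_id) {
  tag <- sub("/[12]$", "", sub("^[^:]*:[^:]*::", "", read_id))
  f <- function(key) sub(paste0(".*", key, "=([^;]*).*"), "\\1", tag)
  junc <- f("junc")
  tibble(read_id = read_id,
         mol = f("mol"), ins = f("ins"), end = f("end"), kind = f("kind"),
         junc_contig = sub(":[^:]*$", "", junc),
         junc = suppressWarnings(as.integer(sub("^.*:", "", junc))))
}

#' Simulate per-locus count tables directly
#'
#' A count-level companion to the read simulator for statistical
#' experiments: per-locus abundance weights are log-normal (mirroring the
#' tens-fold CPM spread between loci), present loci receive Poisson counts
#' proportional to their weight, and absent loci receive a small Poisson
#' "leak" (mis-mapped reads; absent loci are always mapped by a few reads
#' rather than none).
#'
#' @param n_fixed,n_polymorphic Locus counts.
#' @param n_individuals,n_replicates Design.
#' @param library_size Uniquely-mapped flank count per sample (CPM
#'   denominator).
#' @param leak_mean Expected stray count at an absent locus per replicate.
#' @param allele_frequency Carrier allele frequency for polymorphic loci.
#' @param sdlog Log-normal spread of per-locus abundance.
#' @param seed Integer seed.
#' @return List with `quant` (long tibble: `sample_id`, `locus_id`, `count`,
#'   `library_size`), `samples`, and `truth` (per-locus polymorphism and
#'   per-individual presence).
#' @export
simulate_quant_tables <- function(n_fixed = 200L, n_polymorphic = 10L,
                                  n_individuals = 2L, n_replicates = 3L,
                                  library_size = 100000L, leak_mean = 0.2,
                                  allele_frequency = 0.5, sdlog = 1,
                                  seed = 1L) {
  if (n_individuals < 2 && n_polymorphic > 0)
    abort("polymorphic loci need >= 2 individuals")
  with_seed(seed, {
    n <- n_fixed + n_polymorphic
    loci <- tibble(
      locus_id = sprintf("locus%03d", seq_len(n)),
      polymorphic = rep(c(FALSE, TRUE), c(n_fixed, n_polymorphic)),
      weight = rlnorm(n, 0, sdlog))
    individuals <- sprintf("ind%02d", seq_len(n_individuals))
    presence <- tidyr::expand_grid(individual = individuals,
                                   locus_id = loci$locus_id) |>
      left_join(loci, by = "locus_id") |>
      group_by(.data$locus_id) |>
      mutate(present = if (first(.data$polymorphic)) {
        repeat {
          pr <- rbinom(n(), 2, allele_frequency) > 0
          if (any(pr) && any(!pr)) break
        }
        pr
      } else TRUE) |>
      ungroup() |>
      select("individual", "locus_id", "present")
    samples <- tidyr::expand_grid(individual = individuals,
                                  replicate = seq_len(n_replicates)) |>
      mutate(sample_id = sprintf("%s_r%d", .data$individual,
                                 .data$replicate)) |>
      relocate("sample_id")
    mean_per_unit <- library_size / sum(loci$weight)
    loci$expected_count <- loci$weight * mean_per_unit + leak_mean
    quant <- tidyr::expand_grid(sample_id = samples$sample_id,
                                locus_id = loci$locus_id) |>
      left_join(samples, by = "sample_id") |>
      left_join(presence, by = c("individual", "locus_id")) |>
      left_join(select(loci, "locus_id", "weight"), by = "locus_id") |>
      mutate(mu = if_else(.data$present,
                          .data$weight * mean_per_unit + leak_mean,
                          leak_mean),
             count = rpois(n(), .data$mu),
             library_size = as.integer(library_size)) |>
      select("sample_id", "locus_id", "count", "library_size")
    list(quant = quant, samples = samples,
         truth = list(loci = loci, presence = presence))
  })
}

#' Write simulated read pairs as gzipped FASTQ
#'
#' @param pairs Tibble from [simulate_reads()] (one sample or several; a
#'   file pair is written per `sample_id`).
#' @param dir Output directory.
#' @return Tibble of written paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- pairs |>
    group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      f1 <- file.path(dir, paste0(key$sample_id, "_R1.fastq.gz"))
      f2 <- file.path(dir, paste0(key$sample_id, "_R2.fastq.gz"))
      s1 <- Biostrings::DNAStringSet(df$seq1); names(s1) <- df$read_id
      s2 <- Biostrings::DNAStringSet(df$seq2); names(s2) <- df$read_id
      Biostrings::writeXStringSet(
        s1, f1, format = "fastq", compress = TRUE,
        qualities = Biostrings::BStringSet(df$qual1))
      Biostrings::writeXStringSet(
        s2, f2, format = "fastq", compress = TRUE,
        qualities = Biostrings::BStringSet(df$qual2))
      tibble(sample_id = key$sample_id, r1 = f1, r2 = f2)
    }) |>
    bind_rows()
  invisible(written)
}

#' Read paired FASTQ files into the pair-table form
#'
#' @param r1,r2 FASTQ paths (gzip supported).
#' @param sample_id Sample label to attach.
#' @return Tibble in the [simulate_reads()] layout.
#' @export
read_fastq_pairs <- function(r1, r2, sample_id = "sample") {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(s1) != length(s2)) abort("R1/R2 read counts differ")
  tibble(sample_id = sample_id,
         read_id = sub(" .*", "", names(s1)),
         seq1 = unname(as.character(s1)),
         qual1 = unname(as.character(S4Vectors::mcols(s1)$qualities)),
         seq2 = unname(as.character(s2)),
         qual2 = unname(as.character(S4Vectors::mcols(s2)$qualities)))
}

#' Write genome sequences as FASTA
#'
#' @param seqs Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
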