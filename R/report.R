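# Pipeline orchestration and evaluation statistics: replicate
# repeatability, chi-square comparison of detection counts, CPM
# correlations, and the age-vs-CPM summary.

#' Pipeline configuration
#'
#' All stage parameters with their defaults: 20-bp baits at 90% identity,
#' 10-nt flank minimum, 10-nt catalog window, 2-kb novel-locus distance,
#' CPM >= 50 detection filter, fold change > 20 with p < 1e-10 for
#' polymorphism calls. The configuration is echoed into every output.
#'
#' @param bait_len,min_identity Bait matching parameters.
#' @param min_flank Minimum flank length after linker stripping.
#' @param window_nt Catalog assignment window (nt).
#' @param min_novel_dist Minimum distance of novel loci from the catalog.
#' @param cluster_gap,min_reads Novel-cluster parameters.
#' @param max_tsd Maximum target-site-duplication length.
#' @param cpm_min CPM detection threshold.
#' @param fc_min,p_max,pseudocount Polymorphism thresholds.
#' @param max_mismatch_frac Aligner mismatch allowance.
#' @param index_k Aligner seed length.
#' @param trim_window,trim_mean_q,trim_min_len Quality-trim parameters.
#' @param merge_min_overlap,merge_max_mismatch Pair-merge parameters.
#' @param subsample_depths Depth ladder for [saturation()].
#' @param seed Integer seed.
#' @return An `ltr_config` list.
#' @export
pipeline_config <- function(bait_len = 20L, min_identity = 0.90,
                            min_flank = 10L, window_nt = 10L,
                            min_novel_dist = 2000L, cluster_gap = 50L,
                            min_reads = 2L, max_tsd = 10L, cpm_min = 50,
                            fc_min = 20, p_max = 1e-10, pseudocount = 0.5,
                            max_mismatch_frac = 0.06, index_k = 15L,
                            trim_window = 4L, trim_mean_q = 15,
                            trim_min_len = 36L, merge_min_overlap = 10L,
                            merge_max_mismatch = 0.1,
                            subsample_depths = c(1e3, 5e3, 1e4, 2e4, 3e4,
                                                 5e4, 7e4, 1e5, 1.5e5),
                            seed = 1L) {
  stopifnot_scalar_number(min_identity, "min_identity", 0.5, 1)
  stopifnot_scalar_number(window_nt, "window_nt", 0)
  stopifnot_scalar_number(cpm_min, "cpm_min", 0)
  stopifnot_scalar_number(fc_min, "fc_min", 1)
  stopifnot_scalar_number(p_max, "p_max", 0, 1)
  cfg <- list(bait_len = as.integer(bait_len), min_identity = min_identity,
              min_flank = as.integer(min_flank),
              window_nt = as.integer(window_nt),
              min_novel_dist = as.integer(min_novel_dist),
              cluster_gap = as.integer(cluster_gap),
              min_reads = as.integer(min_reads),
              max_tsd = as.integer(max_tsd), cpm_min = cpm_min,
              fc_min = fc_min, p_max = p_max, pseudocount = pseudocount,
              max_mismatch_frac = max_mismatch_frac,
              index_k = as.integer(index_k),
              trim_window = as.integer(trim_window),
              trim_mean_q = trim_mean_q,
              trim_min_len = as.integer(trim_min_len),
              merge_min_overlap = as.integer(merge_min_overlap),
              merge_max_mismatch = merge_max_mismatch,
              subsample_depths = as.integer(subsample_depths),
              seed = as.integer(seed))
  structure(cfg, class = "ltr_config")
}

#' Run the per-sample pipeline on one pair table
#'
#' Read preparation, chimera detection, flank mapping and catalog
#' assignment/quantification for a single sample.
#'
#' @param pairs Raw pair table for one sample.
#' @param catalog A `hervk_catalog`.
#' @param index An `ltr_genome_index` of the reference assembly.
#' @param config An `ltr_config`.
#' @param baitset,linker_seq,hervk_seqs Chimera-stage inputs; defaults come
#'   from the packaged synthetic element set and protocol.
#' @param sample_id Sample label.
#' @return List: `quant`, `assigned`, `unassigned`, `alignments`,
#'   `metrics`.
#' @export
process_sample <- function(pairs, catalog, index,
                           config = pipeline_config(),
                           baitset = NULL, linker_seq = NULL,
                           hervk_seqs = NULL, sample_id = NULL) {
  elements <- hml2_elements()
  baitset <- baitset %||% bait_set(elements = elements,
                                   bait_len = config$bait_len,
                                   min_identity = config$min_identity)
  linker_seq <- linker_seq %||% default_protocol()$linker_seq
  hervk_seqs <- hervk_seqs %||% c(elements$ltr, internal = elements$internal)
  sample_id <- sample_id %||% (pairs$sample_id[1] %||% "sample")

  reads <- prep_reads(
    pairs,
    trim = list(window = config$trim_window, mean_q = config$trim_mean_q,
                min_len = config$trim_min_len),
    merge = list(min_overlap = config$merge_min_overlap,
                 max_mismatch_ratio = config$merge_max_mismatch))
  flanks <- find_chimeras(reads, baitset, linker_seq, hervk_seqs,
                          min_flank = config$min_flank)
  al <- align_flanks(flanks, index,
                     max_mismatch_frac = config$max_mismatch_frac)
  uniq <- filter(al, .data$status == "unique")
  asg <- assign_to_catalog(al, catalog, window_nt = config$window_nt)
  library_size <- nrow(uniq)
  quant <- if (library_size > 0) {
    quantify(asg$counts, library_size, cpm_min = config$cpm_min,
             sample_id = sample_id)
  } else {
    asg$counts |>
      mutate(sample_id = sample_id, library_size = 0L, cpm = 0,
             detected = FALSE, detected_filtered = FALSE) |>
      relocate("sample_id")
  }
  list(quant = quant, assigned = asg$assigned, unassigned = asg$unassigned,
       alignments = al,
       metrics = list(prep = attr(reads, "metrics"),
                      chimera = attr(flanks, "metrics"),
                      n_flanks = nrow(flanks),
                      n_unique = library_size,
                      n_multi = sum(al$status == "multi_mapped"),
                      n_unmapped = sum(al$status == "unmapped"),
                      n_ties = asg$n_ties))
}

#' Run the full pipeline over all samples
#'
#' Executes read preparation, chimera detection, flank mapping and locus
#' calling per sample, pools unassigned junctions for novel-locus
#' discovery and classification, and (with at least two individuals) runs
#' the polymorphic-locus scan. With `outdir` set, per-sample quant TSVs, a
#' novel-locus table, contrast tables, run metrics and the configuration
#' are written with provenance headers. Reruns with the same inputs and
#' configuration are deterministic.
#'
#' @param pairs Pair table across samples (`sample_id` column) as from
#'   [simulate_reads()].
#' @param catalog A `hervk_catalog`.
#' @param genome Reference assembly: named character vector, FASTA path or
#'   prebuilt `ltr_genome_index`.
#' @param samples Sample sheet; derived from `pairs` when absent.
#' @param config An `ltr_config`.
#' @param baitset,linker_seq,hervk_seqs Optional chimera-stage overrides.
#' @param ltr_annotation Optional annotated-LTR track for novel-reference
#'   classification.
#' @param outdir Optional output directory.
#' @return An `ltr_run` list: `quant` (all samples, long), per-sample
#'   `metrics`, `novel` calls, `scan` (polymorphic scan or `NULL`),
#'   `config`, `samples`.
#' @export
run_pipeline <- function(pairs, catalog, genome, samples = NULL,
                         config = pipeline_config(), baitset = NULL,
                         linker_seq = NULL, hervk_seqs = NULL,
                         ltr_annotation = NULL, outdir = NULL) {
  index <- if (inherits(genome, "ltr_genome_index")) genome
           else build_index(genome, k = config$index_k)
  if (is.null(samples)) {
    samples <- tibble(sample_id = unique(pairs$sample_id)) |>
      mutate(individual = .data$sample_id, replicate = 1L)
  }
  per <- purrr::map(samples$sample_id, function(sid) {
    process_sample(filter(pairs, .data$sample_id == sid), catalog, index,
                   config, baitset = baitset, linker_seq = linker_seq,
                   hervk_seqs = hervk_seqs, sample_id = sid)
  })
  names(per) <- samples$sample_id
  quant <- bind_rows(purrr::map(per, "quant"))
  unassigned <- bind_rows(purrr::map(per, "unassigned"))
  clusters <- discover_novel(unassigned, catalog,
                             min_novel_dist = config$min_novel_dist,
                             cluster_gap = config$cluster_gap,
                             min_reads = config$min_reads,
                             window_nt = config$window_nt)
  novel <- classify_novel(clusters, max_tsd = config$max_tsd,
                          ltr_annotation = ltr_annotation,
                          window_nt = config$window_nt)
  scan <- NULL
  if (length(unique(samples$individual)) >= 2) {
    scan <- pairwise_scan(quant, samples, fc_min = config$fc_min,
                          p_max = config$p_max,
                          pseudocount = config$pseudocount)
  }
  run <- structure(list(quant = quant, clusters = clusters, novel = novel,
                        scan = scan, samples = samples, config = config,
                        metrics = purrr::map(per, "metrics")),
                   class = "ltr_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.ltr_run <- function(x, ...) {
  cat(sprintf(
    "# ltr_run: %d samples, %d catalog loci, %d novel calls%s\n",
    nrow(x$samples), length(unique(x$quant$locus_id)), nrow(x$novel),
    if (!is.null(x$scan))
      sprintf(", %d polymorphic loci", sum(x$scan$summary$polymorphic))
    else ""))
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# ltrmapr run | seed=%d | config=%s",
                 run$config$seed,
                 jsonlite::toJSON(unclass(run$config), auto_unbox = TRUE))
  for (sid in run$samples$sample_id) {
    f <- file.path(outdir, paste0(sid, "_quant.tsv"))
    writeLines(hdr, f)
    suppressWarnings(readr::write_tsv(
      filter(run$quant, .data$sample_id == sid), f, append = TRUE,
      col_names = TRUE))
  }
  f <- file.path(outdir, "novel_loci.tsv")
  writeLines(hdr, f)
  suppressWarnings(readr::write_tsv(run$novel, f, append = TRUE,
                                    col_names = TRUE))
  if (!is.null(run$scan)) {
    f <- file.path(outdir, "polymorphic_contrasts.tsv")
    writeLines(hdr, f)
    suppressWarnings(readr::write_tsv(tidy(run$scan), f, append = TRUE,
                                      col_names = TRUE))
  }
  jsonlite::write_json(
    list(config = unclass(run$config),
         samples = run$samples,
         metrics = run$metrics),
    file.path(outdir, "run_metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Replicate repeatability summary
#'
#' Venn-style detection counts for one individual's replicates: per
#' replicate, detected in all replicates, and detected in any replicate —
#' both unfiltered (count >= 1) and CPM-filtered.
#'
#' @param quant Long quantification table for >= 2 replicate samples.
#' @return Tibble with `what` (sample id, `all_replicates`,
#'   `any_replicate`), `n_detected`, `n_detected_filtered`.
#' @export
repeatability_summary <- function(quant) {
  sids <- unique(quant$sample_id)
  if (length(sids) < 2) abort("need >= 2 replicates")
  sets <- function(col) {
    purrr::map(sids, function(s)
      quant$locus_id[quant$sample_id == s & quant[[col]]])
  }
  s_raw <- sets("detected")
  s_flt <- sets("detected_filtered")
  tibble(
    what = c(sids, "all_replicates", "any_replicate"),
    n_detected = c(lengths(s_raw),
                   length(purrr::reduce(s_raw, intersect)),
                   length(purrr::reduce(s_raw, union))),
    n_detected_filtered = c(lengths(s_flt),
                            length(purrr::reduce(s_flt, intersect)),
                            length(purrr::reduce(s_flt, union))))
}

#' Chi-square comparison of detection counts across replicates
#'
#' Tests whether the number of detected loci differs among replicates.
#' The default treats replicates as a 2 x k contingency table of detected
#' vs undetected loci out of the locus universe (Pearson chi-square,
#' k - 1 df); `method = "gof"` instead tests the detected counts for
#' equality as a goodness-of-fit to equal proportions.
#'
#' @param counts_detected Detected-locus count per replicate.
#' @param universe_size Size of the locus universe (>= max count).
#' @param method `"contingency"` (default) or `"gof"`.
#' @return Tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chisq_detection <- function(counts_detected, universe_size,
                            method = c("contingency", "gof")) {
  method <- match.arg(method)
  if (universe_size <= 0) abort("universe_size must be > 0")
  if (length(counts_detected) < 2) abort("need >= 2 replicates")
  if (any(counts_detected > universe_size))
    abort("universe_size must be >= every detected count")
  if (method == "contingency") {
    tab <- rbind(detected = counts_detected,
                 undetected = universe_size - counts_detected)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  } else {
    ht <- suppressWarnings(chisq.test(counts_detected))
  }
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = if (unname(ht$statistic) == 0) 1 else unname(ht$p.value),
         method = method)
}

#' Pairwise Pearson correlation of locus CPMs
#'
#' Correlations are computed over the union of loci detected in any
#' sample, with absent entries as 0 (convention recorded in the result).
#' Zero-variance samples yield `NA` entries.
#'
#' @param quant Long quantification table for >= 2 samples.
#' @param filtered Use the CPM-filtered detection union.
#' @return An `ltr_cor` correlation matrix (diagonal 1).
#' @export
cpm_correlation <- function(quant, filtered = FALSE) {
  det_col <- if (filtered) "detected_filtered" else "detected"
  keep <- unique(quant$locus_id[quant[[det_col]]])
  wide <- quant |>
    filter(.data$locus_id %in% keep) |>
    select("sample_id", "locus_id", "cpm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cpm",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2) abort("need >= 2 samples")
  cc <- suppressWarnings(cor(m, method = "pearson"))
  diag(cc) <- 1
  structure(cc, class = c("ltr_cor", class(cc)),
            convention = "CPM over detection union; absent = 0")
}

#' Mean CPM by element age bin
#'
#' Buckets catalogued loci by estimated age (half-open bins `[lo, hi)`),
#' reports mean and median of the per-locus average CPM across samples,
#' and a Spearman rank correlation of age vs CPM (attribute `"rho"`). With
#' the amplification bias of the enrichment protocol, mean CPM decreases
#' with age: recent integrations are easier to detect.
#'
#' @param quant Long quantification table.
#' @param catalog A `hervk_catalog` with `est_age_mya` annotations.
#' @param breaks Ascending age-bin boundaries (Mya).
#' @return Tibble `age_bin`, `n_loci`, `mean_cpm`, `median_cpm`; attribute
#'   `"rho"` holds the rank correlation.
#' @export
age_cpm_summary <- function(quant, catalog,
                            breaks = c(0, 5, 10, 15, 20, Inf)) {
  ages <- as_tibble(catalog) |>
    select("locus_id", "est_age_mya") |>
    filter(!is.na(.data$est_age_mya))
  if (nrow(ages) == 0) {
    warn("no age-annotated loci")
    return(tibble(age_bin = character(), n_loci = integer(),
                  mean_cpm = numeric(), median_cpm = numeric()))
  }
  per_locus <- quant |>
    group_by(.data$locus_id) |>
    summarise(mean_cpm = mean(.data$cpm)) |>
    inner_join(ages, by = "locus_id")
  rho <- suppressWarnings(cor(per_locus$est_age_mya, per_locus$mean_cpm,
                              method = "spearman"))
  out <- per_locus |>
    mutate(age_bin = cut(.data$est_age_mya, breaks = breaks,
                         right = FALSE, include.lowest = FALSE)) |>
    group_by(.data$age_bin) |>
    summarise(n_loci = n(), mean_cpm = mean(.data$mean_cpm),
              median_cpm = median(.data$mean_cpm)) |>
    mutate(age_bin = as.character(.data$age_bin))
  attr(out, "rho") <- rho
  out
}
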