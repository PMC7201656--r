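# Catalog of known HERV-K (HML-2) integration loci.
#
# Internal convention: 0-based half-open intervals on "chr"-prefixed,
# lower-case contig names (unplaced contigs such as "Un_gl000212" are kept
# verbatim). Table-style listings are declared 1-based inclusive and
# converted on load.

CATALOG_COLS <- c("locus_id", "contig", "start", "end", "strand",
                  "element_type", "ltr_subtype", "catalog_status",
                  "polymorphic_annotation", "population_frequency",
                  "est_age_mya", "gene_context")

ELEMENT_TYPES    <- c("provirus", "solo_LTR")
LTR_SUBTYPES     <- c("LTR5_Hs", "LTR5A", "LTR5B", "other", "unknown")
CATALOG_STATUSES <- c("reference", "non_reference",
                      "novel_reference", "novel_non_reference")
POLY_ANNOTATIONS <- c("fixed", "polymorphic", "unknown")

# Maximum internal span allowed for a non-reference record: the target-site
# duplication footprint.
MAX_NONREF_SPAN <- 10L

#' Normalise a contig name
#'
#' Contigs spelled with a leading "chr" (any case) are lower-cased to the
#' "chr"-prefixed form; other names (e.g. unplaced "Un_gl000212"-style
#' contigs) are kept verbatim.
#'
#' @param x Character vector of contig names.
#' @return Character vector.
#' @export
normalize_contig <- function(x) {
  pref <- grepl("^chr", x, ignore.case = TRUE)
  x[pref] <- paste0("chr", sub("^chr", "", x[pref], ignore.case = TRUE))
  x
}

#' Assemble a locus catalog from a records table
#'
#' Validates a table of integration-locus records (0-based half-open
#' coordinates) and stamps it as a `hervk_catalog`. Missing optional columns
#' (`polymorphic_annotation`, `population_frequency`, `est_age_mya`,
#' `gene_context`) are filled with their "unknown"/`NA` defaults.
#'
#' @param records Data frame with at least `locus_id`, `contig`, `start`,
#'   `end`, `strand`, `element_type`, `ltr_subtype`, `catalog_status`.
#' @param source Character vector of provenance strings.
#' @return A `hervk_catalog` tibble.
#' @export
as_catalog <- function(records, source = character()) {
  records <- as_tibble(records)
  need <- c("locus_id", "contig", "start", "end", "strand",
            "element_type", "ltr_subtype", "catalog_status")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("catalog records lack required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"polymorphic_annotation" %in% names(records))
    records$polymorphic_annotation <- "unknown"
  if (!"population_frequency" %in% names(records))
    records$population_frequency <- NA_real_
  if (!"est_age_mya" %in% names(records))
    records$est_age_mya <- NA_real_
  if (!"gene_context" %in% names(records))
    records$gene_context <- NA_character_

  records <- records |>
    mutate(contig = normalize_contig(.data$contig),
           start = as.integer(.data$start),
           end = as.integer(.data$end)) |>
    select(dplyr::all_of(CATALOG_COLS))

  validate_catalog_records(records)
  structure(records,
            class = c("hervk_catalog", class(tibble())),
            coordinate_system = "zero_half_open",
            source_files = source)
}

validate_catalog_records <- function(records) {
  check_tokens <- function(col, allowed) {
    bad <- setdiff(unique(records[[col]]), allowed)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s token(s): %s (allowed: %s)",
                    col, paste(bad, collapse = ", "),
                    paste(allowed, collapse = ", ")))
    }
  }
  check_tokens("element_type", ELEMENT_TYPES)
  check_tokens("ltr_subtype", LTR_SUBTYPES)
  check_tokens("catalog_status", CATALOG_STATUSES)
  check_tokens("polymorphic_annotation", POLY_ANNOTATIONS)
  check_tokens("strand", c("+", "-", "unknown"))
  if (any(is.na(records$contig) | records$contig == ""))
    abort("catalog records must have non-empty contigs")
  bad <- which(records$start >= records$end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end after normalization for locus %s",
                  records$locus_id[bad[1]]))
  }
  dup <- records$locus_id[duplicated(records$locus_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate locus_id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  nonref <- records$catalog_status %in% c("non_reference",
                                          "novel_non_reference")
  wide <- nonref & (records$end - records$start) > MAX_NONREF_SPAN
  if (any(wide)) {
    abort(sprintf(
      "non-reference record %s spans %d bp; at most %d bp (a target-site duplication footprint) is allowed",
      records$locus_id[which(wide)[1]],
      records$end[which(wide)[1]] - records$start[which(wide)[1]],
      MAX_NONREF_SPAN))
  }
  bad_freq <- !is.na(records$population_frequency) &
    (records$population_frequency < 0 | records$population_frequency > 1)
  if (any(bad_freq)) abort("population_frequency must lie in [0, 1]")
  bad_age <- !is.na(records$est_age_mya) & records$est_age_mya < 0
  if (any(bad_age)) abort("est_age_mya must be >= 0")
  invisible(records)
}

#' @export
print.hervk_catalog <- function(x, ...) {
  cat(sprintf("# HERV-K (HML-2) locus catalog: %d records (%s coordinates)\n",
              nrow(x), attr(x, "coordinate_system")))
  NextMethod()
}

parse_coordinate_field <- function(x, line_no) {
  m <- regmatches(x, regexec("^\\s*([^:]+):\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(sprintf("malformed coordinate '%s' on line %d",
                  x[which(bad)[1]], line_no[which(bad)[1]]))
  }
  tibble(contig = vapply(m, `[`, character(1), 2),
         start1 = as.integer(vapply(m, `[`, character(1), 3)),
         end1 = as.integer(vapply(m, `[`, character(1), 4)))
}

#' Load a locus catalog from a TSV or BED file
#'
#' Two dialects are supported. `table_s1_tsv` is a tab-separated listing with
#' columns `locus_id`, `coordinate` (`"Chr6: 32643459-32643464"` style,
#' declared 1-based inclusive), `orientation` (`(+)`, `(-)`, `+`, `-` or
#' `unknown`), `type`, `status`, `subtype`, and optional `frequency`,
#' `age_mya`, `gene_context`. `bed6plus` is BED6 (0-based half-open) with the
#' extra columns `element_type`, `catalog_status`, `ltr_subtype`,
#' `polymorphic_annotation`, `population_frequency`, `est_age_mya`,
#' `gene_context` appended. Lines starting with `#` are ignored. All records
#' are normalised to the internal 0-based half-open convention.
#'
#' @param path File path.
#' @param dialect One of `"table_s1_tsv"`, `"bed6plus"`.
#' @return A `hervk_catalog` tibble.
#' @export
load_catalog <- function(path, dialect = c("table_s1_tsv", "bed6plus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))

  if (dialect == "table_s1_tsv") {
    raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    need <- c("locus_id", "coordinate", "orientation", "type", "status",
              "subtype")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("table_s1_tsv file lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (nrow(raw) == 0) return(as_catalog(empty_records(), source = path))
    line_no <- seq_len(nrow(raw)) + 1L
    coords <- parse_coordinate_field(raw$coordinate, line_no)
    strand <- gsub("[()]", "", raw$orientation)
    strand[strand %in% c("", ".", NA)] <- "unknown"
    records <- tibble(
      locus_id = raw$locus_id,
      contig = coords$contig,
      start = coords$start1 - 1L,   # 1-based inclusive -> 0-based half-open
      end = coords$end1,
      strand = strand,
      element_type = raw$type,
      ltr_subtype = raw$subtype,
      catalog_status = raw$status,
      population_frequency =
        if ("frequency" %in% names(raw)) as.numeric(raw$frequency) else NA_real_,
      est_age_mya =
        if ("age_mya" %in% names(raw)) as.numeric(raw$age_mya) else NA_real_,
      gene_context =
        if ("gene_context" %in% names(raw)) raw$gene_context else NA_character_
    )
    if ("polymorphic_annotation" %in% names(raw))
      records$polymorphic_annotation <- raw$polymorphic_annotation
  } else {
    raw <- readr::read_tsv(
      path, comment = "#", show_col_types = FALSE,
      col_names = c("contig", "start", "end", "locus_id", "score", "strand",
                    "element_type", "catalog_status", "ltr_subtype",
                    "polymorphic_annotation", "population_frequency",
                    "est_age_mya", "gene_context"),
      col_types = readr::cols(.default = "c"))
    if (nrow(raw) == 0) return(as_catalog(empty_records(), source = path))
    strand <- raw$strand
    strand[strand %in% c(".", "", NA)] <- "unknown"
    records <- tibble(
      locus_id = raw$locus_id,
      contig = raw$contig,
      start = as.integer(raw$start),
      end = as.integer(raw$end),
      strand = strand,
      element_type = raw$element_type,
      ltr_subtype = raw$ltr_subtype,
      catalog_status = raw$catalog_status,
      polymorphic_annotation = raw$polymorphic_annotation,
      population_frequency = suppressWarnings(as.numeric(raw$population_frequency)),
      est_age_mya = suppressWarnings(as.numeric(raw$est_age_mya)),
      gene_context = raw$gene_context
    )
  }
  if (anyNA(records$start) || anyNA(records$end)) {
    bad <- which(is.na(records$start) | is.na(records$end))[1]
    abort(sprintf("malformed coordinates on line %d", bad + 1L))
  }
  as_catalog(records, source = path)
}

empty_records <- function() {
  tibble(locus_id = character(), contig = character(),
         start = integer(), end = integer(), strand = character(),
         element_type = character(), ltr_subtype = character(),
         catalog_status = character(),
         polymorphic_annotation = character(),
         population_frequency = numeric(), est_age_mya = numeric(),
         gene_context = character())
}

#' Write a locus catalog
#'
#' Writes either the table dialect (coordinates converted back to 1-based
#' inclusive) or BED6+ (0-based half-open). A header comment names the
#' coordinate convention; [load_catalog()] round-trips both dialects.
#'
#' @param catalog A `hervk_catalog`.
#' @param path Output file.
#' @param dialect One of `"table_s1_tsv"`, `"bed6plus"`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path,
                          dialect = c("table_s1_tsv", "bed6plus")) {
  dialect <- match.arg(dialect)
  if (dialect == "table_s1_tsv") {
    out <- tibble(
      locus_id = catalog$locus_id,
      coordinate = sprintf("%s: %d-%d", catalog$contig,
                           catalog$start + 1L, catalog$end),
      orientation = if_else(catalog$strand %in% c("+", "-"),
                            paste0("(", catalog$strand, ")"), "unknown"),
      type = catalog$element_type,
      status = catalog$catalog_status,
      subtype = catalog$ltr_subtype,
      polymorphic_annotation = catalog$polymorphic_annotation,
      frequency = catalog$population_frequency,
      age_mya = catalog$est_age_mya,
      gene_context = catalog$gene_context
    )
    writeLines("# coordinates: 1-based inclusive", path)
    suppressWarnings(readr::write_tsv(out, path, append = TRUE,
                                      col_names = TRUE, na = ""))
  } else {
    out <- tibble(
      contig = catalog$contig, start = catalog$start, end = catalog$end,
      locus_id = catalog$locus_id, score = 0L,
      strand = if_else(catalog$strand %in% c("+", "-"), catalog$strand, "."),
      element_type = catalog$element_type,
      catalog_status = catalog$catalog_status,
      ltr_subtype = catalog$ltr_subtype,
      polymorphic_annotation = catalog$polymorphic_annotation,
      population_frequency = catalog$population_frequency,
      est_age_mya = catalog$est_age_mya,
      gene_context = catalog$gene_context
    )
    writeLines("# coordinates: 0-based half-open (BED)", path)
    suppressWarnings(readr::write_tsv(out, path, append = TRUE,
                                      col_names = FALSE, na = ""))
  }
  invisible(path)
}

#' Count catalog records by category
#'
#' Tallies records by `catalog_status` x `element_type`. The counts always
#' sum to the total record count, which is attached as attribute `"total"`.
#'
#' @param catalog A `hervk_catalog`.
#' @return Tibble with columns `catalog_status`, `element_type`, `n`.
#' @export
count_by_category <- function(catalog) {
  tab <- as_tibble(catalog) |>
    count(.data$catalog_status, .data$element_type, name = "n") |>
    arrange(.data$catalog_status, .data$element_type)
  attr(tab, "total") <- nrow(catalog)
  tab
}

catalog_category_count <- function(counts, status, type) {
  hit <- counts$catalog_status == status & counts$element_type == type
  if (!any(hit)) 0L else sum(counts$n[hit])
}

.query_warned <- new.env(parent = emptyenv())

#' Query catalog loci around a genomic position
#'
#' Returns every record whose interval, expanded by `window_nt` on both
#' sides, contains `position` (0-based). A position at exactly `window_nt`
#' from an interval edge is included. Unknown contigs yield an empty result
#' (reported once per contig, not an error).
#'
#' @param catalog A `hervk_catalog`.
#' @param contig Contig name.
#' @param position 0-based position.
#' @param window_nt Non-negative window in nucleotides.
#' @return Tibble of matching records (possibly empty).
#' @export
query_window <- function(catalog, contig, position, window_nt = 10L) {
  if (window_nt < 0) abort("window_nt must be >= 0")
  contig <- normalize_contig(contig)
  on_contig <- catalog$contig == contig
  if (!any(on_contig)) {
    if (is.null(.query_warned[[contig]])) {
      .query_warned[[contig]] <- TRUE
      inform(paste0("query_window: contig not in catalog: ", contig))
    }
    return(as_tibble(catalog)[0, ])
  }
  sub <- as_tibble(catalog)[on_contig, ]
  # [start - w, end + w) contains position  <=>  1-based overlap below
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(start = sub$start + 1L - window_nt,
                     end = sub$end + window_nt),
    IRanges::IRanges(start = position + 1L, width = 1L))
  sub[hits, ]
}

#' Merge novel loci into a catalog
#'
#' Extends the catalog with novel records (`catalog_status` must be
#' `novel_reference` or `novel_non_reference`). A novel record lying within
#' `window_nt` of an existing record is rejected as a duplicate of a known
#' locus and listed in the `"merge_report"` attribute rather than merged.
#' Colliding `locus_id`s are an error.
#'
#' @param catalog A `hervk_catalog`.
#' @param novel Data frame of novel locus records.
#' @param window_nt Proximity window for duplicate rejection.
#' @return Extended `hervk_catalog`; attribute `"merge_report"` is a tibble
#'   of rejected records with a `reason` column.
#' @export
merge_novel <- function(catalog, novel, window_nt = 10L) {
  novel <- as_tibble(novel)
  if (nrow(novel) == 0) {
    attr(catalog, "merge_report") <- tibble(locus_id = character(),
                                            reason = character())
    return(catalog)
  }
  bad_status <- setdiff(unique(novel$catalog_status),
                        c("novel_reference", "novel_non_reference"))
  if (length(bad_status) > 0) {
    abort(paste0("novel records must have a novel_* catalog_status, got: ",
                 paste(bad_status, collapse = ", ")))
  }
  novel <- as_catalog(novel)
  clash <- intersect(novel$locus_id, catalog$locus_id)
  if (length(clash) > 0) {
    abort(paste0("locus_id collision(s): ", paste(clash, collapse = ", ")))
  }
  near <- vapply(seq_len(nrow(novel)), function(i) {
    sub <- catalog[catalog$contig == novel$contig[i], , drop = FALSE]
    if (nrow(sub) == 0) return(FALSE)
    gap <- pmax(sub$start - novel$end[i], novel$start[i] - sub$end, 0L)
    any(gap <= window_nt)
  }, logical(1))
  report <- tibble(locus_id = novel$locus_id[near],
                   reason = "duplicate-of-known")
  merged <- as_catalog(bind_rows(as_tibble(catalog), as_tibble(novel)[!near, ]),
                       source = attr(catalog, "source_files"))
  attr(merged, "merge_report") <- report
  merged
}
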