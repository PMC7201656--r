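# Polymorphic-locus calling between individuals: a conditional-binomial
# exact test on replicate-summed counts combined with a CPM fold-change
# rule (fold change > 20 and p < 1e-10 by default).

#' Conditional binomial exact test for two count totals
#'
#' Conditional on the total `t = ya + yb`, `ya` is Binomial(t, Na/(Na+Nb))
#' under the null of equal relative abundance in the two libraries. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one (with the customary `1 + 1e-7` relative slack for
#' floating-point ties); `t = 0` gives p = 1. This is the
#' dispersion-to-zero limit of a negative-binomial exact test.
#'
#' @param ya,yb Summed counts in the two individuals.
#' @param na,nb Summed library sizes (> 0).
#' @return Two-sided p-value in `(0, 1]`. Vectorised over `ya`/`yb`.
#' @export
exact_count_test <- function(ya, yb, na, nb) {
  if (any(na <= 0) || any(nb <= 0)) abort("library sizes must be > 0")
  if (any(ya > na) || any(yb > nb)) abort("counts cannot exceed library sizes")
  n <- max(length(ya), length(yb))
  ya <- rep_len(ya, n); yb <- rep_len(yb, n)
  na <- rep_len(na, n); nb <- rep_len(nb, n)
  vapply(seq_len(n), function(i) {
    t <- ya[i] + yb[i]
    if (t == 0) return(1)
    pr <- na[i] / (na[i] + nb[i])
    d <- dbinom(0:t, t, pr)
    keep <- d <= d[ya[i] + 1] * (1 + 1e-7)
    if (all(keep)) return(1)   # observed outcome is modal: no evidence
    min(1, max(sum(d[keep]), d[ya[i] + 1]))
  }, numeric(1))
}

#' CPM fold change
#'
#' Fold change reported as max/min, so always >= 1.
#'
#' @param a,b Mean CPM values (> 0).
#' @return `pmax(a, b) / pmin(a, b)`.
#' @export
fold_change <- function(a, b) {
  pmax(a, b) / pmin(a, b)
}

#' Call polymorphic loci between two individuals
#'
#' Per locus: replicate CPMs are computed with a pseudocount added to each
#' replicate count (keeping fold changes finite even for absent loci,
#' which in practice attract a few stray reads rather than none), averaged
#' per individual, and compared as max/min fold change; the p-value comes
#' from [exact_count_test()] on replicate-summed counts and library sizes.
#' A locus is `polymorphic` when fold change > `fc_min` AND p < `p_max`;
#' all loci are reported with their call flag.
#'
#' @param quant_a,quant_b Long quantification tables (columns `sample_id`,
#'   `locus_id`, `count`, `library_size`) for the replicates of the two
#'   individuals; the locus universes must match.
#' @param individual_a,individual_b Labels for the output.
#' @param fc_min Fold-change threshold.
#' @param p_max p-value threshold.
#' @param pseudocount Added to each replicate count before CPM.
#' @return Contrast tibble: `locus_id`, `individual_a`, `individual_b`,
#'   `mean_cpm_a`, `mean_cpm_b`, `cpm_fold_change`, `p_value`, `call`.
#' @export
call_polymorphic <- function(quant_a, quant_b,
                             individual_a = "A", individual_b = "B",
                             fc_min = 20, p_max = 1e-10,
                             pseudocount = 0.5) {
  ua <- sort(unique(quant_a$locus_id)); ub <- sort(unique(quant_b$locus_id))
  if (!identical(ua, ub)) {
    diff_loci <- c(setdiff(ua, ub), setdiff(ub, ua))
    abort(paste0("locus universes differ between individuals: ",
                 paste(head(diff_loci, 10), collapse = ", ")))
  }
  summarise_ind <- function(q) {
    q |>
      mutate(cpm = (.data$count + pseudocount) / .data$library_size * 1e6) |>
      group_by(.data$locus_id) |>
      summarise(mean_cpm = mean(.data$cpm), y = sum(.data$count),
                n = sum(.data$library_size[!duplicated(.data$sample_id)]))
  }
  a <- summarise_ind(quant_a)
  b <- summarise_ind(quant_b)
  tab <- inner_join(a, b, by = "locus_id", suffix = c("_a", "_b"))
  tab |>
    mutate(individual_a = individual_a, individual_b = individual_b,
           cpm_fold_change = fold_change(.data$mean_cpm_a, .data$mean_cpm_b),
           p_value = exact_count_test(.data$y_a, .data$y_b,
                                      .data$n_a, .data$n_b),
           call = if_else(.data$cpm_fold_change > fc_min &
                            .data$p_value < p_max,
                          "polymorphic", "not_polymorphic")) |>
    select("locus_id", "individual_a", "individual_b",
           mean_cpm_a = "mean_cpm_a", mean_cpm_b = "mean_cpm_b",
           "cpm_fold_change", "p_value", "call")
}

#' Scan all individual pairs for polymorphic loci
#'
#' Runs [call_polymorphic()] for every unordered pair of individuals and
#' summarises, per locus, the set of pairs in which it is called (union
#' semantics: a locus is polymorphic if called in at least one pair).
#'
#' @param quant Long quantification table across all samples.
#' @param samples Sample sheet (`sample_id`, `individual`, `replicate`).
#' @param fc_min,p_max,pseudocount Thresholds as in [call_polymorphic()].
#' @return An `ltr_polymorphic_scan` with elements `contrasts` (all pairs,
#'   long), `summary` (per-locus union calls) and `thresholds`. `tidy()`
#'   returns the contrasts, `glance()` the headline counts, and
#'   `autoplot()` a volcano plot.
#' @export
pairwise_scan <- function(quant, samples, fc_min = 20, p_max = 1e-10,
                          pseudocount = 0.5) {
  individuals <- unique(samples$individual)
  if (length(individuals) < 2) abort("need >= 2 individuals")
  prs <- utils::combn(individuals, 2, simplify = FALSE)
  quant <- left_join(quant, select(samples, "sample_id", "individual"),
                     by = "sample_id")
  contrasts <- purrr::map_dfr(prs, function(pr) {
    call_polymorphic(filter(quant, .data$individual == pr[1]),
                     filter(quant, .data$individual == pr[2]),
                     individual_a = pr[1], individual_b = pr[2],
                     fc_min = fc_min, p_max = p_max,
                     pseudocount = pseudocount)
  })
  summary <- contrasts |>
    group_by(.data$locus_id) |>
    summarise(
      n_pairs_called = sum(.data$call == "polymorphic"),
      pairs = paste(sprintf("%s-%s", .data$individual_a,
                            .data$individual_b)[.data$call == "polymorphic"],
                    collapse = ";"),
      polymorphic = any(.data$call == "polymorphic"))
  structure(list(contrasts = contrasts, summary = summary,
                 thresholds = list(fc_min = fc_min, p_max = p_max,
                                   pseudocount = pseudocount)),
            class = "ltr_polymorphic_scan")
}

#' @export
print.ltr_polymorphic_scan <- function(x, ...) {
  cat(sprintf(
    "# polymorphic-locus scan: %d loci, %d pair contrasts, %d loci called (FC > %g & p < %g)\n",
    nrow(x$summary), nrow(x$contrasts) / nrow(x$summary),
    sum(x$summary$polymorphic), x$thresholds$fc_min, x$thresholds$p_max))
  invisible(x)
}

#' @rdname pairwise_scan
#' @param x An `ltr_polymorphic_scan`.
#' @param ... Unused.
#' @method tidy ltr_polymorphic_scan
#' @export
tidy.ltr_polymorphic_scan <- function(x, ...) {
  x$contrasts |>
    mutate(log2_fold_change = log2(.data$cpm_fold_change),
           neg_log10_p = -log10(pmax(.data$p_value, 1e-300)))
}

#' @rdname pairwise_scan
#' @method glance ltr_polymorphic_scan
#' @export
glance.ltr_polymorphic_scan <- function(x, ...) {
  tibble(n_loci = nrow(x$summary),
         n_pairs = length(unique(paste(x$contrasts$individual_a,
                                       x$contrasts$individual_b))),
         n_polymorphic = sum(x$summary$polymorphic),
         fc_min = x$thresholds$fc_min,
         p_max = x$thresholds$p_max)
}
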